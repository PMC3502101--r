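uniform_freqs <- function(aas) {
  gc <- standard_genetic_code()
  structure(lapply(stats::setNames(nm = aas), function(a) {
    fam <- gc$families[[a]]
    stats::setNames(rep(1 / length(fam), length(fam)), fam)
  }), class = "genome_codon_frequencies")
}

test_that("gene volatility sums per-codon volatilities", {
  expect_equal(gene_volatility(make_cds(c("ATG", "TGG")))[c("v_sum", "v_mean")],
               list(v_sum = 2, v_mean = 1))
  expect_equal(gene_volatility(make_cds(c("AGA", "AGA")))$v_sum, 1.5)
  expect_equal(gene_volatility(make_cds("AGA"),
                               model = mutation_model(4.1))$v_sum,
               12.2 / 17.3)
})

test_that("genome codon frequencies are per-family probabilities", {
  cds_list <- list(make_cds(c("AGA", "AGA", "CGT", "AAA"), "x"),
                   make_cds(c("AAA", "AAG", "TGG"), "y"))
  fr <- codon_frequencies(cds_list)
  expect_true(all(abs(vapply(fr, sum, numeric(1)) - 1) < 1e-12))
  expect_equal(unname(fr$K[c("AAA", "AAG")]), c(2, 1) / 3)
  expect_equal(unname(fr$R["AGA"]), 2 / 3)
  expect_false(any(grepl("TAA|TAG|TGA", unlist(lapply(fr, names)))))
})

test_that("null moments are exact: full-enumeration oracle on a short protein", {
  fr <- uniform_freqs(c("R", "G", "K"))
  # oracle: enumerate every synonymous encoding of RGK with its probability
  gcf <- standard_genetic_code()$families
  combos <- expand.grid(r = gcf$R, g = gcf$G, k = gcf$K,
                        stringsAsFactors = FALSE)
  v <- apply(combos, 1, function(row) sum(vapply(row, oracle_volatility, 0)))
  p <- rep(1 / nrow(combos), nrow(combos))
  nm <- null_moments("RGK", fr)
  expect_equal(nm$null_mean, sum(p * v), tolerance = 1e-12)
  expect_equal(nm$null_var, sum(p * v^2) - sum(p * v)^2, tolerance = 1e-12)
})

test_that("null moments handle degenerate and missing cases", {
  fr <- uniform_freqs(c("M", "W", "R"))
  nm <- null_moments("MW", fr)
  expect_equal(nm$null_var, 0)
  expect_equal(nm$null_mean, 2)  # both single-codon families have volatility 1
  expect_equal(null_moments("R", fr)$null_mean,
               mean(vapply(standard_genetic_code()$families$R,
                           oracle_volatility, 0)))
  expect_error(null_moments("RX", fr), "X")
  expect_error(null_moments("R*", fr), "stop")
})

test_that("P-value orientation and degenerate nulls behave", {
  fr <- uniform_freqs(c("M", "W", "R"))
  mw <- validate_cds("ATGTGG", "mw")
  for (method in c("exact_normal", "monte_carlo")) {
    res <- volatility_pvalue(mw, fr, method = method, n_samples = 1000,
                             seed = 1)
    expect_equal(res$p_value, 1)
    expect_equal(res$v_mean, res$v_sum / res$n_codons)
  }
  # re-encoding a protein with its most volatile synonyms gives the
  # smallest P among encodings of that protein
  vt <- volatility_table()
  fam <- standard_genetic_code()$families$R
  hi <- fam[which.max(vt[fam])]
  lo <- fam[which.min(vt[fam])]
  p_hi <- volatility_pvalue(make_cds(rep(hi, 30)), fr)$p_value
  p_lo <- volatility_pvalue(make_cds(rep(lo, 30)), fr)$p_value
  expect_lt(p_hi, p_lo)
})

test_that("monte_carlo and exact_normal agree in the body of the null", {
  g <- toy_genome(n_genes = 30, min_codons = 300, max_codons = 300,
                  seed = 21, gc3_sd = 0)
  vs <- validate_cds_set(g$sequences)
  fr <- codon_frequencies(vs$cds)
  devs <- c()
  for (cds in vs$cds[1:12]) {
    ex <- volatility_pvalue(cds, fr, method = "exact_normal")
    if (ex$p_value < 0.05 || ex$p_value > 0.95) next
    mc <- volatility_pvalue(cds, fr, method = "monte_carlo",
                            n_samples = 1e5, seed = 99)
    devs <- c(devs, abs(mc$p_value - ex$p_value))
  }
  expect_gte(length(devs), 3)
  # the residual discrepancy is the normal approximation's skewness error
  # at 300 codons (Monte-Carlo error at 1e5 samples is ~0.002)
  expect_lt(max(devs), 0.03)
  expect_lt(median(devs), 0.01)
})

test_that("P-value is invariant to codon order within a gene", {
  fr <- uniform_freqs(c("R", "G", "K", "L"))
  codons <- c("AGA", "GGG", "AAA", "CTT", "CGA", "GGA")
  p1 <- volatility_pvalue(make_cds(codons), fr)$p_value
  p2 <- volatility_pvalue(make_cds(rev(codons)), fr)$p_value
  set.seed(4); p3 <- volatility_pvalue(make_cds(sample(codons)), fr)$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("genome scan is deterministic and ranks a forced volatile gene first", {
  g <- toy_genome(n_genes = 25, min_codons = 80, max_codons = 150, seed = 8)
  vs <- validate_cds_set(g$sequences)
  s1 <- volatility_scan(vs$cds, method = "monte_carlo", n_samples = 2000,
                        seed = 123)
  s2 <- volatility_scan(vs$cds, method = "monte_carlo", n_samples = 2000,
                        seed = 123)
  expect_identical(s1$results, s2$results)

  # same protein everywhere; one gene re-encoded maximally volatile
  vt <- volatility_table(model = mutation_model(4.1))
  gc <- standard_genetic_code()
  base <- vs$cds[[1]]
  prot <- strsplit(translate_cds(base), "")[[1]]
  reencode <- function(pick, id) {
    codons <- vapply(prot, function(a) pick(gc$families[[a]]), "")
    structure(list(gene_id = id, codons = codons, source_note = ""),
              class = "cds")
  }
  set.seed(11)
  cohort <- c(lapply(1:10, function(i)
    reencode(function(f) sample(f, 1), paste0("rand", i))),
    list(reencode(function(f) f[which.max(vt[f])], "maxvol")))
  names(cohort) <- vapply(cohort, `[[`, "", "gene_id")
  sc <- volatility_scan(cohort)
  expect_identical(sc$results$gene_id[which.min(sc$results$p_value)], "maxvol")
  expect_error(volatility_scan(cohort[1]), "at least 2")
})

test_that("scan output table satisfies its own invariants", {
  g <- toy_genome(n_genes = 20, seed = 31)
  vs <- validate_cds_set(g$sequences)
  sc <- volatility_scan(vs$cds)
  df <- sc$results
  expect_equal(df$v_mean, df$v_sum / df$n_codons)
  expect_true(all(df$p_value >= 0 & df$p_value <= 1))
  expect_true(all(df$null_var >= 0))
  expect_identical(df$elevated_flag, df$p_value < sc$threshold)
  expect_output(print(sc), "genes scored")
  expect_output(print(summary(sc)), "quartiles")
})
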