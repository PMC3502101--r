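test_that("codon counting conserves totals", {
  cc <- count_codons(make_cds(c("ATG", "AAA")))
  expect_equal(sum(cc), 2)
  expect_equal(unname(cc[c("ATG", "AAA")]), c(1L, 1L))
  expect_equal(unname(count_codons(make_cds(c("AGA", "AGA")))["AGA"]), 2L)
  g <- toy_genome(n_genes = 5, seed = 2)
  for (cds in validate_cds_set(g$sequences)$cds)
    expect_equal(sum(count_codons(cds)), length(cds$codons))
})

test_that("RSCU normalizes within families and flags missing ones", {
  gc <- standard_genetic_code()
  arg <- gc$families$R
  rs <- rscu(count_codons(make_cds(arg)))
  expect_equal(unname(rs$values[arg]), rep(1, 6))

  rs2 <- rscu(count_codons(make_cds(rep("AGA", 6))))
  expect_equal(unname(rs2$values["AGA"]), 6)
  expect_equal(unname(rs2$values[setdiff(arg, "AGA")]), rep(0, 5))

  rs3 <- rscu(count_codons(make_cds(c("AAA", "GGG"))))
  expect_true("R" %in% rs3$missing_families)
  expect_true(all(is.na(rs3$values[arg])))

  # family-mean normalization across random genes
  g <- toy_genome(n_genes = 8, seed = 13)
  for (cds in validate_cds_set(g$sequences)$cds) {
    rs <- rscu(count_codons(cds))
    for (aa in setdiff(names(gc$families), rs$missing_families)) {
      fam <- gc$families[[aa]]
      if (length(fam) < 2) next
      expect_equal(mean(rs$values[fam]), 1, tolerance = 1e-12)
    }
  }
})

test_that("GC3 is computed over degenerate codons only", {
  expect_true(is.na(gc3(make_cds(c("ATG", "TGG")))))
  expect_equal(gc3(make_cds(c("GCC", "GCA"))), 0.5)
  expect_equal(gc3(make_cds(c("AAA", "AAG", "ATG"))), 0.5)  # ATG excluded
})

test_that("ENC attains its theoretical extremes and bounds", {
  gc <- standard_genetic_code()
  # one codon per amino acid, large counts -> maximal bias, Nc = 20
  one_each <- unlist(lapply(gc$families, `[`, 1))
  nc_min <- enc(count_codons(make_cds(rep(one_each, 50))))
  expect_equal(nc_min, 20, tolerance = 0.05)
  # uniform use of all codons, large counts -> Nc near 61
  all_uniform <- unlist(gc$families)
  nc_max <- enc(count_codons(make_cds(rep(all_uniform, 40))))
  expect_gt(nc_max, 60.5)
  # bounds on random genes; self-concatenation leaves ENC unchanged
  # asymptotically (Wright's homozygosity carries a 1/n bias correction,
  # so the comparison is made at large counts)
  g <- toy_genome(n_genes = 6, min_codons = 1000, max_codons = 1200, seed = 3)
  for (cds in validate_cds_set(g$sequences)$cds) {
    nc1 <- enc(count_codons(cds))
    expect_true(nc1 >= 20 && nc1 <= 61)
    big <- make_cds(rep(cds$codons, 16))
    bigger <- make_cds(rep(cds$codons, 32))
    expect_lt(abs(enc(count_codons(bigger)) - enc(count_codons(big))), 0.1)
  }
  # no degenerate family with 2+ codons -> missing
  expect_true(is.na(enc(count_codons(make_cds(c("ATG", "TGG"))))))
})

test_that("correspondence analysis matches an eigen-decomposition oracle", {
  x <- matrix(c(3, 1, 2,
                1, 4, 1,
                2, 2, 5,
                4, 1, 1), nrow = 4, byrow = TRUE)
  ca <- codon_ca(x)
  # oracle: eigenvalues of S'S for the standardized residual matrix
  P <- x / sum(x)
  E <- outer(rowSums(P), colSums(P))
  S <- (P - E) / sqrt(E)
  ev <- sort(eigen(crossprod(S), symmetric = TRUE)$values, decreasing = TRUE)
  ev <- ev[ev > 1e-12]
  expect_equal(sort(ca$singular_values^2, decreasing = TRUE), ev,
               tolerance = 1e-10)
  expect_equal(ca$total_inertia, sum(ev), tolerance = 1e-10)
  expect_equal(sum(ca$inertia_fraction), 1, tolerance = 1e-12)
  # chi-square identity: total inertia = X^2 / grand total
  chi <- suppressWarnings(stats::chisq.test(x))$statistic
  expect_equal(ca$total_inertia, unname(chi) / sum(x), tolerance = 1e-10)
})

test_that("correspondence analysis agrees with MASS::corresp", {
  skip_if_not_installed("MASS")
  set.seed(7)
  x <- matrix(rpois(60, 8) + 1, nrow = 10)
  ca <- codon_ca(x)
  cr <- MASS::corresp(x, nf = 2)
  expect_equal(ca$singular_values[1:2], unname(cr$cor[1:2]), tolerance = 1e-8)
  # principal column coordinates agree up to sign
  ours <- ca$column_coordinates[, 1]
  theirs <- cr$cscore[, 1] * cr$cor[1]
  expect_equal(abs(unname(ours)), abs(unname(theirs)), tolerance = 1e-8)
})

test_that("degenerate and duplicated CA inputs behave as contracts state", {
  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  ca0 <- codon_ca(same)
  expect_equal(ca0$total_inertia, 0)
  expect_equal(ncol(ca0$row_coordinates), 0)

  set.seed(9)
  x <- matrix(runif(45, 0.2, 3), nrow = 9)
  ca1 <- codon_ca(x)
  ca2 <- codon_ca(rbind(x, x))
  expect_equal(ca2$column_coordinates, ca1$column_coordinates,
               tolerance = 1e-9)
  expect_equal(ca2$inertia_fraction, ca1$inertia_fraction, tolerance = 1e-9)
  expect_error(codon_ca(x[1:2, ]), "3 rows")
})

test_that("usage_axes separates planted codon-usage regimes on Axis 1", {
  low <- toy_genome(n_genes = 60, min_codons = 150, max_codons = 250,
                    seed = 5, gc3_bias = 0.25, gc3_sd = 0.03)
  high <- toy_genome(n_genes = 60, min_codons = 150, max_codons = 250,
                     seed = 6, gc3_bias = 0.75, gc3_sd = 0.03)
  seqs <- c(low$sequences, high$sequences)
  names(seqs) <- sprintf("g%03d", seq_along(seqs))
  vs <- validate_cds_set(seqs)
  ua <- usage_axes(vs$cds)
  regime <- rep(c(0, 1), each = 60)
  expect_gt(abs(cor(ua$table$axis1, regime)), 0.8)
  expect_output(print(ua), "Axis 1")
})

test_that("usage_axes applies the 100 bp length filter and is deterministic", {
  g <- toy_genome(n_genes = 10, min_codons = 50, max_codons = 80, seed = 17)
  vs <- validate_cds_set(g$sequences)
  short <- structure(list(gene_id = "short33",
                          codons = vs$cds[[1]]$codons[1:33],  # 99 bp
                          source_note = ""), class = "cds")
  cohort <- c(vs$cds, list(short33 = short))
  ua <- usage_axes(cohort, min_bp = 100)
  expect_identical(ua$excluded$gene_id, "short33")
  expect_false("short33" %in% ua$table$gene_id)
  ua2 <- usage_axes(cohort, min_bp = 100)
  expect_identical(ua$table, ua2$table)
  expect_error(usage_axes(cohort[1:2]), "fewer than 3|3 rows")
})

test_that("GC3 responds monotonically to the generator's bias parameter", {
  levels <- seq(0.3, 0.7, by = 0.1)
  mean_gc3 <- vapply(seq_along(levels), function(i) {
    g <- toy_genome(n_genes = 30, min_codons = 100, max_codons = 150,
                    seed = 100 + i, gc3_bias = levels[i], gc3_sd = 0.02)
    vs <- validate_cds_set(g$sequences)
    mean(vapply(vs$cds, gc3, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_gc3) > 0))
  expect_gt(cor(levels, mean_gc3, method = "spearman"), 0.9)
})
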