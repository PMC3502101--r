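codon_aln <- function(c1, c2, ids = c("a", "b"),
                      ref = c(sum(c1 != "---"), sum(c2 != "---"))) {
  structure(list(codons1 = c1, codons2 = c2, gene_ids = ids,
                 ref_codons = ref), class = "codon_alignment")
}

test_that("protein alignment scores follow the BLOSUM62 table", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  ident <- align_proteins("MKV", "MKV", mode = "global")
  expect_identical(ident$aligned1, "MKV")
  expect_equal(ident$score,
               BLOSUM62["M", "M"] + BLOSUM62["K", "K"] + BLOSUM62["V", "V"])
  # one mismatch column; gapped alternatives cost >= 2 gap openings and
  # cannot beat the diagonal, so the optimum is the mismatch alignment
  mm <- align_proteins("MKV", "MRV", mode = "global")
  expect_identical(mm$aligned1, "MKV")
  expect_identical(mm$aligned2, "MRV")
  expect_equal(mm$score,
               BLOSUM62["M", "M"] + BLOSUM62["K", "R"] + BLOSUM62["V", "V"])
  # local mode extracts exactly the embedded block
  loc <- align_proteins("AAAMKVAAA", "MKV", mode = "local")
  expect_identical(loc$aligned1, "MKV")
  expect_equal(loc$start1, 4)
  expect_error(align_proteins("", "MKV"), "empty")
})

test_that("back-translation preserves the residue-codon correspondence", {
  cds1 <- make_cds(c("ATG", "AAA", "GTT"), "a")
  cds2 <- make_cds(c("ATG", "AGA", "GTG"), "b")
  pa <- align_proteins(translate_cds(cds1), translate_cds(cds2),
                       mode = "global")
  ca <- backtranslate_alignment(pa, cds1, cds2)
  expect_identical(ca$codons1, cds1$codons)
  expect_identical(ca$codons2, cds2$codons)

  # a protein gap becomes one whole-codon gap
  cds3 <- make_cds(c("ATG", "GTT"), "c")
  pa2 <- align_proteins(translate_cds(cds1), translate_cds(cds3),
                        mode = "global")
  ca2 <- backtranslate_alignment(pa2, cds1, cds3)
  expect_equal(sum(ca2$codons2 == "---"), 1)
  expect_identical(ca2$codons2[ca2$codons2 != "---"], cds3$codons)

  # corrupted CDS: the error names the offending aligned position
  bad <- cds1
  bad$codons[2] <- "CCC"
  expect_error(backtranslate_alignment(pa, bad, cds2),
               "aligned residue 2")
})

test_that("alignment coverage is measured against the named reference", {
  anc <- sample_cds(100, seed = 1, gene_id = "anc")
  frag <- truncate_to_fragment(anc, 0.5, seed = 2)
  pa <- align_proteins(translate_cds(anc), translate_cds(frag),
                       mode = "local")
  ca <- backtranslate_alignment(pa, anc, frag)
  expect_equal(alignment_coverage(ca, reference = 1), 50)
  expect_equal(alignment_coverage(ca, reference = 2), 100)
  full <- backtranslate_alignment(
    align_proteins(translate_cds(anc), translate_cds(anc), mode = "global"),
    anc, anc)
  expect_equal(alignment_coverage(full), 100)
})

test_that("NG86 matches hand-enumerated pathway averaging on a 2-codon toy", {
  # pair (TTT|TTT, CCT|CAG). Site counts: s(TTT) = 1/3, s(CCT) = 1,
  # s(CAG) = 1/3 (TAG excluded as stop), so S = (4/3 + 2/3)/2 = 1, N = 5.
  # CCT->CAG pathways: via CAT gives 2 nonsyn; via CCG gives 1 syn + 1
  # nonsyn; no stop on either path, so Sd = 0.5, Nd = 1.5.
  est <- ng86_dnds(codon_aln(c("TTT", "CCT"), c("TTT", "CAG")))
  expect_equal(est$S, 1, tolerance = 1e-10)
  expect_equal(est$N, 5, tolerance = 1e-10)
  expect_equal(est$Sd, 0.5, tolerance = 1e-10)
  expect_equal(est$Nd, 1.5, tolerance = 1e-10)
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(est$dS, jc(0.5), tolerance = 1e-10)
  expect_equal(est$dN, jc(1.5 / 5), tolerance = 1e-10)
  expect_equal(est$omega, jc(0.3) / jc(0.5), tolerance = 1e-10)
})

test_that("NG86 handles identical, purely synonymous and saturated input", {
  same <- ng86_dnds(codon_aln(c("ATG", "AAA"), c("ATG", "AAA")))
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))

  # synonymous third-position change inside an alignment long enough to
  # stay below the Jukes-Cantor saturation limit
  syn <- ng86_dnds(codon_aln(c(rep("GGG", 10), "TTT"),
                             c(rep("GGG", 10), "TTC")))
  expect_equal(syn$dN, 0)
  expect_gt(syn$dS, 0)

  # a single synonymous difference on 1/3 synonymous sites exceeds the
  # correction limit and must be flagged, not silently repaired
  sat <- ng86_dnds(codon_aln("TTT", "TTC"))
  expect_identical(sat$flag, "saturated")
  expect_true(is.na(sat$dS))
})

test_that("NG86 is symmetric and invariant to appended gap columns", {
  pair <- evolve_pair(sample_cds(200, seed = 5),
                      ortholog_sim_spec(omega = 0.5, kappa = 2, t = 0.4,
                                        seed = 6))
  c1 <- pair$ancestor$codons; c2 <- pair$derived$codons
  ab <- ng86_dnds(codon_aln(c1, c2))
  ba <- ng86_dnds(codon_aln(c2, c1))
  expect_equal(ab$dN, ba$dN, tolerance = 1e-12)
  expect_equal(ab$dS, ba$dS, tolerance = 1e-12)

  gapped <- ng86_dnds(codon_aln(c(c1, "AAA", "---"), c(c2, "---", "CCC")))
  expect_equal(gapped$dN, ab$dN, tolerance = 1e-12)
  expect_equal(gapped$dS, ab$dS, tolerance = 1e-12)
})

test_that("M0 fit drives divergence time to zero on identical sequences", {
  cds <- sample_cds(300, seed = 9)
  fit <- m0_fit(codon_aln(cds$codons, cds$codons))
  expect_lte(fit$t_hat, 1e-4)
  expect_equal(fit$dN, 0, tolerance = 1e-4)
  expect_equal(fit$dS, 0, tolerance = 1e-4)
  expect_s3_class(logLik(fit), "logLik")
  expect_named(coef(fit), c("t", "kappa", "omega"))
  expect_warning(m0_fit(codon_aln(cds$codons[1:20], cds$codons[1:20])),
                 "noisy")
})

test_that("both estimators rank omega correctly on simulated pairs", {
  omegas <- c(0.1, 0.3, 1.0)
  ng <- m0 <- numeric(3)
  for (i in seq_along(omegas)) {
    pair <- evolve_pair(sample_cds(1500, seed = 40 + i),
                        ortholog_sim_spec(omega = omegas[i], kappa = 4.1,
                                          t = 0.5, seed = 50 + i))
    ca <- codon_aln(pair$ancestor$codons, pair$derived$codons)
    ng[i] <- ng86_dnds(ca)$omega
    fit <- m0_fit(ca)
    m0[i] <- fit$omega
    # optimizer sanity: fitted optimum at least as good as the truth
    expect_gte(fit$logLik, m0_loglik(ca, t = 0.5, kappa = 4.1,
                                     omega = omegas[i]) - 1e-6)
    expect_lt(abs(fit$kappa_hat - 4.1), 1)
  }
  expect_equal(order(ng), 1:3)
  expect_equal(order(m0), 1:3)
  expect_equal(cor(m0, omegas, method = "spearman"), 1)
})

test_that("dnds_pair chains alignment and estimation with coverage", {
  anc <- sample_cds(150, seed = 77, gene_id = "ref")
  pair <- evolve_pair(anc, ortholog_sim_spec(omega = 0.3, kappa = 4.1,
                                             t = 0.3, seed = 78))
  frag <- truncate_to_fragment(pair$derived, 0.4, seed = 79)
  est <- dnds_pair(anc, frag, method = "NG86")
  expect_equal(est$coverage_pct, 40, tolerance = 2)
  expect_identical(est$method, "NG86")
})
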