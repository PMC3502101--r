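# Synthetic genomes, expression tables and diverged ortholog pairs: the two
# competing forces under study -- GC3 mutational bias and translational
# selection -- are both explicit, tunable generator parameters, so every
# pipeline stage and every headline association is testable at desk scale.

# Average-proteome-like amino-acid composition (percent frequencies of the
# 20 residues in a typical well-annotated proteome), used as the default
# protein composition of synthetic genes.
.DEFAULT_AA_COMPOSITION <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

# Plant-like baseline relative usage within each synonymous family (rounded
# relative shares typical of a well-annotated dicot proteome). The GC3
# mutational regime rescales the GC-ending vs AT-ending partition masses
# around this baseline, so unrealistic conventions (e.g. ATA as common as
# ATT) are avoided while the expected third-position G+C fraction equals
# the gene's GC3 target exactly.
.PLANT_FAMILY_USAGE <- c(
  ATT = .41, ATC = .35, ATA = .24,
  AGA = .35, AGG = .20, CGT = .17, CGA = .12, CGG = .09, CGC = .07,
  CTT = .26, CTC = .17, CTG = .11, CTA = .11, TTG = .22, TTA = .14,
  TCT = .28, TCA = .20, TCC = .13, TCG = .10, AGT = .16, AGC = .13,
  GGA = .37, GGT = .34, GGG = .16, GGC = .14,
  GTT = .41, GTG = .26, GTC = .19, GTA = .15,
  CCT = .38, CCA = .33, CCG = .14, CCC = .15,
  ACT = .34, ACA = .31, ACC = .20, ACG = .15,
  GCT = .44, GCA = .27, GCC = .16, GCG = .14,
  TTT = .51, TTC = .49, TAT = .52, TAC = .48, CAT = .61, CAC = .39,
  CAA = .56, CAG = .44, AAT = .52, AAC = .48, AAA = .49, AAG = .51,
  GAT = .68, GAC = .32, GAA = .52, GAG = .48, TGT = .60, TGC = .40,
  ATG = 1, TGG = 1
)

# One designated translationally "optimal" codon per amino acid (a fixed,
# plant-like preferred set; configurable through the genome spec).
.DEFAULT_OPTIMAL_CODONS <- c(
  A = "GCT", R = "AGA", N = "AAC", D = "GAT", C = "TGC", Q = "CAA",
  E = "GAA", G = "GGA", H = "CAT", I = "ATC", L = "CTT", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT"
)

#' Specification of a synthetic genome
#'
#' Collects the generator parameters: gene count, length law, the strength
#' of GC3 mutational bias, the coupling of codon optimality to expression
#' (translational selection), and the expression distribution. Defaults
#' describe a neutral genome with moderate GC3 bias and an RMA-like
#' expression distribution (log2 mean 6.44, SD 2.02).
#'
#' Each gene receives its own GC3 target drawn from a Beta distribution
#' with mean \code{gc3_bias} and standard deviation \code{gc3_sd},
#' emulating the between-gene variation in mutational bias that real
#' genomes show; \code{gc3_sd = 0} gives every gene the same target.
#'
#' @param n_genes number of genes.
#' @param min_codons,max_codons gene length bounds in codons (uniform law);
#'   the minimum must be at least 34 so every gene survives a 100-bp
#'   length filter.
#' @param gc3_bias mean probability, in (0, 1), that a degenerate codon's
#'   third position is G or C under the mutational regime.
#' @param gc3_sd between-gene SD of the per-gene GC3 target (default 0.08).
#' @param selection_strength non-negative coupling of optimal-codon
#'   preference to standardized expression; 0 removes translational
#'   selection entirely.
#' @param expression_mean,expression_sd log2 expression law (defaults
#'   6.44 and 2.02).
#' @param seed integer seed; the whole genome is reproducible from it.
#' @param aa_composition named non-negative vector over the 20 amino acids.
#' @param optimal_codons named codon vector (one per amino acid).
#' @param family_weights named positive vector of baseline within-family
#'   codon usage weights (default: a fixed plant-like profile); the GC3
#'   regime rescales the GC- and AT-ending partition masses around it.
#' @return Object of class \code{synthetic_genome_spec}.
#' @export
synthetic_genome_spec <- function(n_genes = 200L, min_codons = 100L,
                                  max_codons = 400L, gc3_bias = 0.5,
                                  gc3_sd = 0.08, selection_strength = 0,
                                  expression_mean = 6.44,
                                  expression_sd = 2.02, seed = 1L,
                                  aa_composition = .DEFAULT_AA_COMPOSITION,
                                  optimal_codons = .DEFAULT_OPTIMAL_CODONS,
                                  family_weights = .PLANT_FAMILY_USAGE) {
  if (min_codons > max_codons) stop("min_codons exceeds max_codons")
  if (min_codons < 34L) stop("min_codons must be >= 34 (100 bp filter floor)")
  if (gc3_bias <= 0 || gc3_bias >= 1) stop("gc3_bias must be in (0, 1)")
  if (selection_strength < 0) stop("selection_strength must be non-negative")
  structure(list(
    n_genes = as.integer(n_genes), min_codons = as.integer(min_codons),
    max_codons = as.integer(max_codons), gc3_bias = gc3_bias,
    gc3_sd = gc3_sd, selection_strength = selection_strength,
    expression_mean = expression_mean, expression_sd = expression_sd,
    seed = as.integer(seed),
    aa_composition = aa_composition / sum(aa_composition),
    optimal_codons = optimal_codons,
    family_weights = family_weights
  ), class = "synthetic_genome_spec")
}

# Beta parameters from mean m and sd s (method of moments), guarded so the
# requested sd is shrunk if infeasible for the given mean.
.beta_params <- function(m, s) {
  smax <- sqrt(m * (1 - m)) * 0.95
  s <- min(s, smax)
  v <- s^2
  k <- m * (1 - m) / v - 1
  c(a = m * k, b = (1 - m) * k)
}

# GC3-biased codon distribution for one amino-acid family: third-position
# G/C codons share probability g and A/T codons 1 - g, distributed within
# each partition proportionally to the baseline usage weights; single-codon
# families are a point mass. E[GC3] of a draw equals g exactly.
.gc3_family_probs <- function(fam, g, weights = .PLANT_FAMILY_USAGE) {
  if (length(fam) == 1L) return(stats::setNames(1, fam))
  gcend <- substr(fam, 3L, 3L) %in% c("G", "C")
  w <- weights[fam]
  p <- numeric(length(fam))
  p[gcend] <- g * w[fam[gcend]] / sum(w[fam[gcend]])
  p[!gcend] <- (1 - g) * w[fam[!gcend]] / sum(w[fam[!gcend]])
  stats::setNames(p, fam)
}

#' Generate a synthetic genome
#'
#' Draws, per gene, an amino-acid sequence from the spec's composition, a
#' log2 expression value, and a GC3 target; then encodes each residue by
#' mixing a GC3-biased codon distribution (weight 1) with a point mass on
#' the designated optimal codon (weight \code{selection_strength} times the
#' standardized expression, floored at 0). A stop codon is appended to each
#' CDS. Fully reproducible from the spec's seed.
#'
#' @param spec a \code{synthetic_genome_spec}.
#' @param dir optional directory; when given, the CDS FASTA
#'   (\code{genome.fasta}), expression TSV (\code{expression.tsv}), truth
#'   TSV (\code{truth.tsv}) and a run manifest (\code{manifest.tsv}) are
#'   written there.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{synthetic_genome}: list with
#'   \code{sequences} (named character, stop codon included),
#'   \code{expression} (gene_id, log2_expr), \code{truth} (gene_id,
#'   n_codons, gc3_target, selection_weight, log2_expr), and \code{spec}.
#' @export
generate_genome <- function(spec, dir = NULL, code = standard_genetic_code()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  aa_names <- names(spec$aa_composition)
  .with_seed(spec$seed, {
    lens <- sample(spec$min_codons:spec$max_codons, spec$n_genes, replace = TRUE)
    expr <- stats::rnorm(spec$n_genes, spec$expression_mean, spec$expression_sd)
    g_target <- if (spec$gc3_sd > 0) {
      bp <- .beta_params(spec$gc3_bias, spec$gc3_sd)
      stats::rbeta(spec$n_genes, bp["a"], bp["b"])
    } else rep(spec$gc3_bias, spec$n_genes)
    z <- (expr - spec$expression_mean) / spec$expression_sd
    w <- pmax(0, spec$selection_strength * z)
    ids <- sprintf("synth_g%05d", seq_len(spec$n_genes))
    seqs <- character(spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      prot <- sample(aa_names, lens[i], replace = TRUE,
                     prob = spec$aa_composition)
      codons <- character(lens[i])
      for (aa in unique(prot)) {
        fam <- code$families[[aa]]
        p <- .gc3_family_probs(fam, g_target[i], spec$family_weights)
        opt <- spec$optimal_codons[[aa]]
        p_mix <- (p + w[i] * (names(p) == opt)) / (1 + w[i])
        at <- which(prot == aa)
        codons[at] <- sample(names(p_mix), length(at), replace = TRUE,
                             prob = p_mix)
      }
      seqs[i] <- paste(c(codons, "TAA"), collapse = "")
    }
    names(seqs) <- ids
    out <- structure(list(
      sequences = seqs,
      expression = data.frame(gene_id = ids, log2_expr = expr,
                              stringsAsFactors = FALSE),
      truth = data.frame(gene_id = ids, n_codons = lens,
                         gc3_target = g_target, selection_weight = w,
                         log2_expr = expr, stringsAsFactors = FALSE),
      spec = spec
    ), class = "synthetic_genome")
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_fasta(seqs, file.path(dir, "genome.fasta"))
      write_tsv(out$expression, file.path(dir, "expression.tsv"))
      write_tsv(out$truth, file.path(dir, "truth.tsv"))
      write_tsv(data.frame(
        key = c("n_genes", "min_codons", "max_codons", "gc3_bias", "gc3_sd",
                "selection_strength", "expression_mean", "expression_sd", "seed"),
        value = c(spec$n_genes, spec$min_codons, spec$max_codons, spec$gc3_bias,
                  spec$gc3_sd, spec$selection_strength, spec$expression_mean,
                  spec$expression_sd, spec$seed)
      ), file.path(dir, "manifest.tsv"))
    }
    out
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", length(x$sequences), " genes, gc3_bias = ",
      x$spec$gc3_bias, ", selection_strength = ", x$spec$selection_strength,
      ", seed = ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Sample a random coding sequence from codon frequencies
#'
#' Draws codons independently from an equilibrium distribution over the
#' sense codons; used to create ancestors at the codon model's stationary
#' distribution before [evolve_pair()].
#'
#' @param n_codons gene length in codons.
#' @param pi named probability vector over sense codons (default uniform).
#' @param gene_id identifier.
#' @param seed optional seed.
#' @param code a \code{genetic_code}.
#' @return A validated \code{cds}.
#' @export
sample_cds <- function(n_codons, pi = NULL, gene_id = "random_cds",
                       seed = NULL, code = standard_genetic_code()) {
  if (is.null(pi))
    pi <- stats::setNames(rep(1 / length(code$sense_codons),
                              length(code$sense_codons)), code$sense_codons)
  codons <- .with_seed(seed,
    sample(names(pi), n_codons, replace = TRUE, prob = pi))
  structure(list(gene_id = gene_id, codons = codons,
                 source_note = "sampled from codon frequencies"),
            class = "cds")
}

#' Ortholog pair divergence parameters
#'
#' @param omega positive dN/dS of the simulating process.
#' @param kappa positive transition:transversion rate ratio.
#' @param t expected substitutions per codon separating the pair (>= 0).
#' @param freq_model equilibrium frequency tag: \code{"uniform"} or
#'   \code{"F61"} (empirical frequencies of the ancestral CDS).
#' @param seed integer seed.
#' @return Object of class \code{ortholog_sim_spec}.
#' @export
ortholog_sim_spec <- function(omega = 0.3, kappa = 4.1, t = 0.5,
                              freq_model = c("uniform", "F61"), seed = 1L) {
  freq_model <- match.arg(freq_model)
  if (omega <= 0 || kappa <= 0 || t < 0) stop("need omega > 0, kappa > 0, t >= 0")
  structure(list(omega = omega, kappa = kappa, t = t,
                 freq_model = freq_model, seed = as.integer(seed)),
            class = "ortholog_sim_spec")
}

#' Evolve a diverged copy of a coding sequence
#'
#' Continuous-time simulation (exact Gillespie jumps per codon site) under
#' the 61-state one-ratio codon process: instantaneous rates proportional
#' to pi_j, times kappa for transitions and omega for nonsynonymous
#' changes, no stop states, rate matrix normalized to one expected
#' substitution per codon per unit time. Each site evolves independently
#' for time \code{sim$t}.
#'
#' @param cds validated \code{cds} (the ancestral copy).
#' @param sim an \code{ortholog_sim_spec}.
#' @param code a \code{genetic_code}.
#' @return List with \code{ancestor} (the input) and \code{derived} (a
#'   \code{cds} with suffix \code{"_derived"}).
#' @export
evolve_pair <- function(cds, sim, code = standard_genetic_code()) {
  stopifnot(is_cds(cds), inherits(sim, "ortholog_sim_spec"))
  sense <- code$sense_codons
  pi <- if (sim$freq_model == "F61")
    codon_equilibrium_freqs(cds$codons, "F61", code)
  else
    stats::setNames(rep(1 / length(sense), length(sense)), sense)
  Q <- .codon_Q(pi, sim$kappa, sim$omega, code)
  exit_rate <- -diag(Q)
  state <- match(cds$codons, sense)
  .with_seed(sim$seed, {
    remaining <- rep(sim$t, length(state))
    active <- which(remaining > 0 & exit_rate[state] > 0)
    while (length(active)) {
      dt <- stats::rexp(length(active), exit_rate[state[active]])
      jump <- dt < remaining[active]
      remaining[active] <- remaining[active] - dt
      for (s in active[jump]) {
        rates <- Q[state[s], ]
        rates[state[s]] <- 0
        state[s] <- sample.int(length(sense), 1L, prob = rates)
      }
      active <- active[jump]
      active <- active[exit_rate[state[active]] > 0]
    }
  })
  derived <- structure(list(
    gene_id = paste0(cds$gene_id, "_derived"),
    codons = sense[state],
    source_note = sprintf("evolved under M0: omega=%g kappa=%g t=%g",
                          sim$omega, sim$kappa, sim$t)
  ), class = "cds")
  list(ancestor = cds, derived = derived)
}

#' Truncate a CDS to a contiguous fragment
#'
#' Emulates partial ortholog coverage (shotgun-read fragments): keeps a
#' contiguous window of \code{ceiling(fraction * n)} codons at a seeded
#' random offset.
#'
#' @param cds validated \code{cds}.
#' @param fraction fraction of codons to keep, in (0, 1].
#' @param seed optional seed for the window offset.
#' @return A \code{cds} fragment (gene id suffixed \code{"_frag"}).
#' @export
truncate_to_fragment <- function(cds, fraction, seed = NULL) {
  stopifnot(is_cds(cds))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(cds$codons)
  keep <- as.integer(ceiling(fraction * n))
  if (keep < 1L) stop("fragment would be empty")
  start <- .with_seed(seed, sample.int(n - keep + 1L, 1L))
  structure(list(
    gene_id = paste0(cds$gene_id, "_frag"),
    codons = cds$codons[start:(start + keep - 1L)],
    source_note = sprintf("fragment %d-%d of %s", start, start + keep - 1L,
                          cds$gene_id)
  ), class = "cds")
}
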