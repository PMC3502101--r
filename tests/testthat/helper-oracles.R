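# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: they enumerate from Biostrings' genetic code
# table with plain loops.

.oracle_code <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

# Exhaustive-enumeration codon volatility: weighted fraction of non-stop
# single-base variants encoding a different amino acid.
oracle_volatility <- function(codon, kappa = 1) {
  aa <- .oracle_code[[codon]]
  num <- den <- 0
  for (pos in 1:3) {
    from <- substr(codon, pos, pos)
    for (b in .oracle_bases) {
      if (b == from) next
      nb <- codon
      substr(nb, pos, pos) <- b
      if (.oracle_code[[nb]] == "*") next
      is_ts <- (from %in% c("A", "G")) == (b %in% c("A", "G"))
      w <- if (is_ts) kappa else 1
      den <- den + w
      if (.oracle_code[[nb]] != aa) num <- num + w
    }
  }
  num / den
}

oracle_sense_codons <- sort(names(.oracle_code)[.oracle_code != "*"])

# Closed-form normal-equations OLS.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# One-ratio codon rate matrix built from first principles (uniform
# equilibrium frequencies), normalized to one expected substitution per
# codon per unit time; used with ape::matexpo as the analytic reference
# for the divergence simulator.
oracle_codon_Q_uniform <- function(kappa, omega) {
  sense <- oracle_sense_codons
  n <- length(sense)
  pi <- rep(1 / n, n)
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffs <- which(strsplit(sense[i], "")[[1]] != strsplit(sense[j], "")[[1]])
    if (length(diffs) != 1L) next
    b1 <- substr(sense[i], diffs, diffs)
    b2 <- substr(sense[j], diffs, diffs)
    is_ts <- (b1 %in% c("A", "G")) == (b2 %in% c("A", "G"))
    is_syn <- .oracle_code[[sense[i]]] == .oracle_code[[sense[j]]]
    Q[i, j] <- pi[j] * (if (is_ts) kappa else 1) * (if (is_syn) 1 else omega)
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# Build a tiny validated cds directly from codon strings.
make_cds <- function(codons, id = "toy") {
  validate_cds(paste(codons, collapse = ""), id)
}

# Small synthetic genome shared by several tests.
toy_genome <- function(n_genes = 40, min_codons = 60, max_codons = 120,
                       seed = 42, ...) {
  spec <- synthetic_genome_spec(n_genes = n_genes, min_codons = min_codons,
                                max_codons = max_codons, seed = seed, ...)
  generate_genome(spec)
}
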