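# Gene-level volatility scores and their significance against the
# synonymous re-encoding null.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Genome-wide synonymous codon frequencies
#'
#' Estimates, from a collection of validated coding sequences, the relative
#' frequency of each codon within its synonymous family. These frequencies
#' define the null model for volatility P-values: a gene's protein is
#' re-encoded site by site, drawing each residue's codon from its family's
#' genome-wide frequencies.
#'
#' @param cds_list list of \code{cds} objects.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{genome_codon_frequencies}: a list mapping
#'   each observed amino acid to a named probability vector over its codons
#'   (summing to 1).
#' @export
codon_frequencies <- function(cds_list, code = standard_genetic_code()) {
  stopifnot(length(cds_list) >= 1L, all(vapply(cds_list, is_cds, logical(1))))
  counts <- table(factor(unlist(lapply(cds_list, `[[`, "codons"), use.names = FALSE),
                         levels = code$sense_codons))
  counts <- stats::setNames(as.integer(counts), names(counts))
  out <- list()
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- counts[fam]
    tot <- sum(n)
    if (tot > 0L) out[[aa]] <- n / tot
  }
  structure(out, class = "genome_codon_frequencies")
}

#' Gene-level volatility
#'
#' Sum and mean of per-codon volatilities over a coding sequence; the sum is
#' the gene's overall codon volatility score.
#'
#' @param cds validated \code{cds}.
#' @param model a \code{mutation_model}.
#' @param code a \code{genetic_code}.
#' @return List with \code{v_sum}, \code{v_mean}, \code{n_codons}.
#' @export
gene_volatility <- function(cds, model = mutation_model(1),
                            code = standard_genetic_code()) {
  stopifnot(is_cds(cds))
  if (length(cds$codons) == 0L) stop("empty codon list")
  vt <- volatility_table(code, model)
  v <- vt[cds$codons]
  list(v_sum = sum(v), v_mean = mean(v), n_codons = length(v))
}

# Per-amino-acid null moments of per-site volatility: mean and variance of
# the volatility of a codon drawn from the family's frequency vector.
.aa_null_moments <- function(freqs, vt, code) {
  out <- list()
  for (aa in names(freqs)) {
    p <- freqs[[aa]]
    v <- vt[names(p)]
    m <- sum(p * v)
    out[[aa]] <- c(mean = m, var = sum(p * v^2) - m^2)
  }
  out
}

#' Null moments of the gene volatility score
#'
#' Exact mean and variance of the volatility sum under independent per-site
#' synonymous re-encoding: at each site the residue's codon is drawn from
#' the genome-wide synonymous frequencies, so the null conditions on the
#' protein sequence and moments add across sites.
#'
#' @param protein amino-acid string (one-letter symbols, no stop).
#' @param freqs a \code{genome_codon_frequencies}.
#' @param model a \code{mutation_model}.
#' @param code a \code{genetic_code}.
#' @return List with \code{null_mean} and \code{null_var}.
#' @export
null_moments <- function(protein, freqs, model = mutation_model(1),
                         code = standard_genetic_code()) {
  aas <- strsplit(protein, "")[[1]]
  if (any(aas == "*")) stop("protein contains a stop symbol")
  missing_aa <- setdiff(unique(aas), names(freqs))
  if (length(missing_aa))
    stop("amino acid(s) absent from frequency table: ",
         paste(missing_aa, collapse = ", "))
  vt <- volatility_table(code, model)
  mom <- .aa_null_moments(freqs, vt, code)
  tab <- table(aas)
  m <- sum(vapply(names(tab), function(a) tab[[a]] * mom[[a]]["mean"], numeric(1)))
  v <- sum(vapply(names(tab), function(a) tab[[a]] * mom[[a]]["var"], numeric(1)))
  list(null_mean = unname(m), null_var = unname(v))
}

# Monte-Carlo samples of the null volatility sum for one protein.
# Site draws within an amino acid are iid, so the per-family codon counts of
# a re-encoding are multinomial; one rmultinom call per family replaces
# per-site sampling.
.null_vsum_samples <- function(aa_counts, freqs, vt, n_samples) {
  tot <- numeric(n_samples)
  for (aa in names(aa_counts)) {
    p <- freqs[[aa]]
    v <- vt[names(p)]
    if (length(p) == 1L) {
      tot <- tot + aa_counts[[aa]] * v
    } else {
      draws <- stats::rmultinom(n_samples, aa_counts[[aa]], p)
      tot <- tot + as.numeric(crossprod(draws, v))
    }
  }
  tot
}

#' Volatility P-value for one gene
#'
#' Significance of a gene's volatility sum against the synonymous
#' re-encoding null. The P-value is the null probability of a volatility
#' sum at least as large as observed, so small P means elevated volatility
#' (the orientation under which the genome scan selects elevated genes at
#' P below the threshold).
#'
#' Two methods ship: \code{exact_normal} uses a normal approximation with
#' the exact null mean and variance; \code{monte_carlo} re-encodes the
#' protein \code{n_samples} times and uses the add-one estimator
#' (1 + #\{samples >= observed\}) / (1 + n_samples), which cannot return 0
#' and is the authoritative choice in extreme tails.
#'
#' @param cds validated \code{cds}.
#' @param freqs a \code{genome_codon_frequencies}.
#' @param model a \code{mutation_model}.
#' @param method \code{"exact_normal"} or \code{"monte_carlo"}.
#' @param n_samples Monte-Carlo sample count (>= 1000).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{volatility_result}: list with
#'   \code{gene_id}, \code{v_sum}, \code{v_mean}, \code{null_mean},
#'   \code{null_var}, \code{p_value}, \code{n_codons}, \code{kappa_used},
#'   \code{method}.
#' @export
volatility_pvalue <- function(cds, freqs, model = mutation_model(1),
                              method = c("exact_normal", "monte_carlo"),
                              n_samples = 10000L, seed = NULL,
                              code = standard_genetic_code()) {
  method <- match.arg(method)
  gv <- gene_volatility(cds, model, code)
  prot <- translate_cds(cds, code)
  nm <- null_moments(prot, freqs, model, code)
  eps <- 1e-9
  if (method == "exact_normal") {
    p <- if (nm$null_var <= 0) {
      as.numeric(gv$v_sum <= nm$null_mean + eps)
    } else {
      stats::pnorm(gv$v_sum, nm$null_mean, sqrt(nm$null_var), lower.tail = FALSE)
    }
  } else {
    if (n_samples < 1000L) stop("'n_samples' must be >= 1000 for monte_carlo")
    vt <- volatility_table(code, model)
    aa_counts <- as.list(table(strsplit(prot, "")[[1]]))
    samples <- .with_seed(seed,
      .null_vsum_samples(aa_counts, freqs, vt, n_samples))
    p <- (1 + sum(samples >= gv$v_sum - eps)) / (1 + n_samples)
  }
  structure(list(
    gene_id = cds$gene_id, v_sum = gv$v_sum, v_mean = gv$v_mean,
    null_mean = nm$null_mean, null_var = nm$null_var, p_value = p,
    n_codons = gv$n_codons, kappa_used = model$kappa, method = method
  ), class = "volatility_result")
}

#' @export
print.volatility_result <- function(x, ...) {
  cat("<volatility_result> ", x$gene_id, ": v_sum = ", format(x$v_sum),
      ", P = ", format(x$p_value), " (", x$method, ", kappa = ",
      x$kappa_used, ")\n", sep = "")
  invisible(x)
}

#' Genome-wide volatility scan
#'
#' Scores every gene in a coding-sequence collection and flags those with
#' elevated volatility. Unless an external frequency table is supplied, the
#' synonymous codon frequencies defining the null are estimated from the
#' same gene set being scanned, as a single-genome method requires.
#'
#' @param cds_list list of validated \code{cds} objects (>= 2).
#' @param model a \code{mutation_model}; the genome-scan default kappa is
#'   4.1, the transition:transversion ratio used throughout the package's
#'   reference analysis.
#' @param threshold P-value below which a gene is flagged elevated
#'   (default 1e-6).
#' @param method P-value method, see [volatility_pvalue()].
#' @param n_samples,seed Monte-Carlo settings.
#' @param freqs optional external \code{genome_codon_frequencies}.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{volatility_scan}: list with
#'   \code{results} (one data-frame row per gene: gene_id, n_codons, v_sum,
#'   v_mean, null_mean, null_var, p_value, elevated_flag), \code{freqs},
#'   and the scan settings.
#' @export
volatility_scan <- function(cds_list, model = mutation_model(4.1),
                            threshold = 1e-6,
                            method = c("exact_normal", "monte_carlo"),
                            n_samples = 10000L, seed = NULL, freqs = NULL,
                            code = standard_genetic_code()) {
  method <- match.arg(method)
  if (length(cds_list) < 2L) stop("need at least 2 genes to estimate frequencies")
  if (is.null(freqs)) freqs <- codon_frequencies(cds_list, code)
  run <- function() lapply(cds_list, volatility_pvalue, freqs = freqs,
                           model = model, method = method,
                           n_samples = n_samples, seed = NULL, code = code)
  res <- if (method == "monte_carlo") .with_seed(seed, run()) else run()
  df <- data.frame(
    gene_id = vapply(res, `[[`, "", "gene_id"),
    n_codons = vapply(res, `[[`, 0L, "n_codons"),
    v_sum = vapply(res, `[[`, 0, "v_sum"),
    v_mean = vapply(res, `[[`, 0, "v_mean"),
    null_mean = vapply(res, `[[`, 0, "null_mean"),
    null_var = vapply(res, `[[`, 0, "null_var"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$elevated_flag <- df$p_value < threshold
  structure(list(results = df, freqs = freqs, kappa = model$kappa,
                 threshold = threshold, method = method, seed = seed),
            class = "volatility_scan")
}

#' @export
print.volatility_scan <- function(x, ...) {
  cat("Codon volatility scan\n")
  cat("  genes scored : ", nrow(x$results), "\n", sep = "")
  cat("  kappa        : ", x$kappa, "\n", sep = "")
  cat("  method       : ", x$method, "\n", sep = "")
  cat("  elevated (P < ", format(x$threshold), ") : ",
      sum(x$results$elevated_flag), "\n", sep = "")
  invisible(x)
}

#' @export
summary.volatility_scan <- function(object, ...) {
  df <- object$results
  out <- list(
    n_genes = nrow(df),
    n_elevated = sum(df$elevated_flag),
    threshold = object$threshold,
    kappa = object$kappa,
    v_mean_quartiles = stats::quantile(df$v_mean),
    p_value_quartiles = stats::quantile(df$p_value)
  )
  class(out) <- "summary.volatility_scan"
  out
}

#' @export
print.summary.volatility_scan <- function(x, ...) {
  cat("Codon volatility scan: ", x$n_genes, " genes, ", x$n_elevated,
      " elevated at P < ", format(x$threshold), " (kappa = ", x$kappa, ")\n",
      sep = "")
  cat("per-codon mean volatility quartiles:\n")
  print(round(x$v_mean_quartiles, 4))
  cat("P-value quartiles:\n")
  print(signif(x$p_value_quartiles, 4))
  invisible(x)
}
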