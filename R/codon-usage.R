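# RSCU, ENC, GC3 and correspondence analysis of the 59-dimensional
# synonymous codon usage space.

#' Count codon occurrences in a coding sequence
#'
#' @param cds validated \code{cds}.
#' @param code a \code{genetic_code}.
#' @return Named integer vector over all 64 codons (stop counts are zero by
#'   construction: validation removes them).
#' @export
count_codons <- function(cds, code = standard_genetic_code()) {
  stopifnot(is_cds(cds))
  tab <- table(factor(cds$codons, levels = names(code$codon_to_aa)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Relative synonymous codon usage
#'
#' For a codon in a synonymous family of size k with family total N, RSCU is
#' k * count / N: 1 means the codon is used exactly as often as expected
#' under uniform usage within its family. Only the 59 degenerate codons are
#' scored; families absent from the gene are flagged missing and their RSCU
#' values are NA.
#'
#' @param counts 64-codon count vector from [count_codons()].
#' @param code a \code{genetic_code}.
#' @return List with \code{values} (named numeric over the 59 degenerate
#'   codons, NA for missing families) and \code{missing_families}
#'   (amino-acid symbols with zero family count).
#' @export
rscu <- function(counts, code = standard_genetic_code()) {
  vals <- stats::setNames(rep(NA_real_, length(code$degenerate_codons)),
                          code$degenerate_codons)
  missing_fam <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    if (k < 2L) next
    n <- counts[fam]
    tot <- sum(n)
    if (tot == 0L) {
      missing_fam <- c(missing_fam, aa)
    } else {
      vals[fam] <- k * n / tot
    }
  }
  list(values = vals, missing_families = missing_fam)
}

#' GC content at synonymous third positions (GC3)
#'
#' Fraction of third codon positions that are G or C, computed over the
#' synonymously degenerate codons only (ATG, TGG and stops never
#' contribute).
#'
#' @param cds validated \code{cds}.
#' @param code a \code{genetic_code}.
#' @return Fraction in [0, 1], or NA when the gene has no degenerate codon.
#' @export
gc3 <- function(cds, code = standard_genetic_code()) {
  stopifnot(is_cds(cds))
  deg <- cds$codons[cds$codons %in% code$degenerate_codons]
  if (length(deg) == 0L) return(NA_real_)
  mean(substr(deg, 3L, 3L) %in% c("G", "C"))
}

# Degenerate family classes for Wright's ENC: 2-fold (9 families), 3-fold
# (Ile), 4-fold (5), 6-fold (Leu, Ser, Arg).
.enc_classes <- function(code) {
  sizes <- vapply(code$families, length, integer(1))
  split(names(sizes)[sizes > 1L], sizes[sizes > 1L])
}

#' Wright's effective number of codons (ENC)
#'
#' Wright's (1990) class-based estimator: per degenerate family, the codon
#' homozygosity F = (n * sum(p_i^2) - 1) / (n - 1) is estimated from the
#' family's counts (n = family total); families with n <= 1 or F <= 0 are
#' excluded from their class mean; Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.
#' A class with no estimable family is imputed from the mean of the
#' estimable class means weighted by class family count; the result is
#' clipped to the theoretical range [20, 61].
#'
#' @param counts 64-codon count vector from [count_codons()].
#' @param code a \code{genetic_code}.
#' @return Nc in [20, 61], or NA when no degenerate family is estimable.
#' @export
enc <- function(counts, code = standard_genetic_code()) {
  classes <- .enc_classes(code)
  fbar <- imputed <- stats::setNames(rep(NA_real_, length(classes)), names(classes))
  for (k in names(classes)) {
    fs <- numeric(0)
    for (aa in classes[[k]]) {
      n <- counts[code$families[[aa]]]
      tot <- sum(n)
      if (tot < 2L) next
      f <- (tot * sum((n / tot)^2) - 1) / (tot - 1)
      if (f > 0) fs <- c(fs, f)
    }
    if (length(fs)) fbar[k] <- mean(fs)
  }
  est <- !is.na(fbar)
  if (!any(est)) return(NA_real_)
  if (any(!est)) {
    w <- vapply(classes, length, integer(1))
    fbar[!est] <- sum(w[est] * fbar[est]) / sum(w[est])
  }
  nfam <- vapply(classes, length, integer(1))   # 9, 1, 5, 3 for sizes 2,3,4,6
  nc <- 2 + sum(nfam / fbar)
  min(max(nc, 20), 61)
}

#' Full codon usage profile of one gene
#'
#' @param cds validated \code{cds}.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{codon_usage_profile}: list with
#'   \code{gene_id}, \code{counts} (64), \code{rscu} (59, NA for missing
#'   families), \code{missing_families}, \code{enc}, \code{gc3},
#'   \code{n_degenerate_codons}.
#' @export
codon_usage_profile <- function(cds, code = standard_genetic_code()) {
  counts <- count_codons(cds, code)
  rs <- rscu(counts, code)
  structure(list(
    gene_id = cds$gene_id, counts = counts, rscu = rs$values,
    missing_families = rs$missing_families,
    enc = enc(counts, code), gc3 = gc3(cds, code),
    n_degenerate_codons = sum(counts[code$degenerate_codons])
  ), class = "codon_usage_profile")
}

#' @export
print.codon_usage_profile <- function(x, ...) {
  cat("<codon_usage_profile> ", x$gene_id, ": ", sum(x$counts), " codons, ENC = ",
      round(x$enc, 2), ", GC3 = ", round(x$gc3, 3), "\n", sep = "")
  invisible(x)
}

#' Correspondence analysis of a codon usage matrix
#'
#' Chi-square-metric decomposition of a non-negative genes x codons matrix
#' (typically RSCU values): the matrix is treated as a contingency-style
#' table, standardized residuals (P - rc') / sqrt(rc') are decomposed by
#' SVD, axis inertias are the squared singular values, and total inertia
#' equals the table's chi-square statistic divided by its grand total.
#' Missing cells (NA, from absent families) are set to 0 before
#' decomposition, matching how a zero count behaves in a contingency view.
#'
#' @param x numeric matrix, rows = genes, columns = codons; >= 3 rows.
#' @return Object of class \code{codon_ca}: list with
#'   \code{row_coordinates} and \code{column_coordinates} (principal
#'   coordinates on the retained axes), \code{inertia_fraction},
#'   \code{total_inertia}, \code{singular_values}, \code{n_missing_cells}.
#'   Degenerate input (all rows proportional) yields zero retained axes and
#'   total inertia 0.
#' @export
codon_ca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("correspondence analysis needs at least 3 rows")
  n_missing <- sum(is.na(x))
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("input matrix must be non-negative")
  keep_col <- colSums(x) > 0
  x_used <- x[, keep_col, drop = FALSE]
  grand <- sum(x_used)
  if (grand <= 0) stop("matrix has zero grand total")
  P <- x_used / grand
  r <- rowSums(P)
  cc <- colSums(P)
  if (any(r <= 0)) stop("row(s) with zero total: ",
                        paste(rownames(x)[r <= 0], collapse = ", "))
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d, 0) * 1e-10
  keep <- which(sv$d > tol)
  inertia <- sv$d^2
  total <- sum(inertia)
  if (length(keep) == 0L) {
    row_co <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    col_co <- matrix(0, sum(keep_col), 0, dimnames = list(colnames(x_used), NULL))
    frac <- numeric(0)
  } else {
    d <- sv$d[keep]
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    # deterministic sign: largest-magnitude column loading positive per axis
    for (j in seq_along(keep)) {
      s <- sign(V[which.max(abs(V[, j])), j])
      if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
    }
    row_co <- sweep(U, 1, sqrt(r), "/") %*% diag(d, length(d))
    col_co <- sweep(V, 1, sqrt(cc), "/") %*% diag(d, length(d))
    dimnames(row_co) <- list(rownames(x), paste0("Axis", seq_along(keep)))
    dimnames(col_co) <- list(colnames(x_used), paste0("Axis", seq_along(keep)))
    frac <- inertia[keep] / total
  }
  structure(list(
    row_coordinates = row_co, column_coordinates = col_co,
    inertia_fraction = frac, total_inertia = total,
    singular_values = sv$d[keep], n_missing_cells = n_missing
  ), class = "codon_ca")
}

#' @export
print.codon_ca <- function(x, ...) {
  k <- length(x$inertia_fraction)
  cat("Correspondence analysis: ", nrow(x$row_coordinates), " rows, ",
      k, " retained axes, total inertia ", format(x$total_inertia), "\n",
      sep = "")
  if (k) {
    show <- utils::head(x$inertia_fraction, 5)
    cat("inertia fractions (first ", length(show), "): ",
        paste(sprintf("%.1f%%", 100 * show), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-gene codon usage axes
#'
#' The usage pipeline stage: codon counts, RSCU, ENC, GC3 per gene, then
#' correspondence analysis of the genes x 59 RSCU matrix, reporting each
#' gene's coordinates on the first two axes. Genes shorter than
#' \code{min_bp} (default 100 bp, on the validated CDS without its stop)
#' are excluded and logged. Axes are ranked by inertia; axes with an
#' inertia fraction above \code{significant_inertia} are marked
#' significant.
#'
#' @param cds_list list of validated \code{cds} (>= 3 after filtering).
#' @param min_bp minimum gene length in nucleotides.
#' @param significant_inertia inertia fraction above which an axis is
#'   reported as significant (default 0.05).
#' @param code a \code{genetic_code}.
#' @return Object of class \code{usage_axes}: list with \code{table}
#'   (gene_id, n_codons, enc, gc3, axis1, axis2), \code{ca} (the
#'   \code{codon_ca}), \code{rscu_matrix}, \code{significant_axes},
#'   \code{excluded} (gene_id/reason data frame).
#' @export
usage_axes <- function(cds_list, min_bp = 100, significant_inertia = 0.05,
                       code = standard_genetic_code()) {
  stopifnot(length(cds_list) >= 1L)
  len_bp <- vapply(cds_list, function(z) 3L * length(z$codons), integer(1))
  keep <- len_bp >= min_bp
  excluded <- data.frame(
    gene_id = vapply(cds_list[!keep], `[[`, "", "gene_id"),
    reason = if (any(!keep)) sprintf("length_below_%dbp", as.integer(min_bp)) else character(0),
    stringsAsFactors = FALSE
  )
  cds_list <- cds_list[keep]
  if (length(cds_list) < 3L)
    stop("fewer than 3 genes survive the ", min_bp, " bp length filter")
  profiles <- lapply(cds_list, codon_usage_profile, code = code)
  rs <- t(vapply(profiles, `[[`, numeric(length(code$degenerate_codons)), "rscu"))
  rownames(rs) <- vapply(profiles, `[[`, "", "gene_id")
  ca <- codon_ca(rs)
  # orient axes reproducibly across datasets: GC-ending codon loadings sum
  # to a non-negative value on every reported axis (CA axis signs are
  # otherwise arbitrary)
  gc_end <- substr(rownames(ca$column_coordinates), 3L, 3L) %in% c("G", "C")
  for (j in seq_len(ncol(ca$column_coordinates))) {
    if (sum(ca$column_coordinates[gc_end, j]) < 0) {
      ca$column_coordinates[, j] <- -ca$column_coordinates[, j]
      ca$row_coordinates[, j] <- -ca$row_coordinates[, j]
    }
  }
  k <- ncol(ca$row_coordinates)
  ax1 <- if (k >= 1) ca$row_coordinates[, 1] else rep(0, nrow(rs))
  ax2 <- if (k >= 2) ca$row_coordinates[, 2] else rep(0, nrow(rs))
  tab <- data.frame(
    gene_id = rownames(rs),
    n_codons = vapply(profiles, function(p) sum(p$counts), integer(1)),
    enc = vapply(profiles, `[[`, 0, "enc"),
    gc3 = vapply(profiles, `[[`, 0, "gc3"),
    axis1 = ax1, axis2 = ax2,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    table = tab, ca = ca, rscu_matrix = rs,
    significant_axes = which(ca$inertia_fraction > significant_inertia),
    excluded = excluded
  ), class = "usage_axes")
}

#' @export
print.usage_axes <- function(x, ...) {
  fr <- x$ca$inertia_fraction
  cat("Codon usage axes: ", nrow(x$table), " genes (",
      nrow(x$excluded), " excluded by length filter)\n", sep = "")
  if (length(fr) >= 2)
    cat(sprintf("  Axis 1: %.1f%% inertia, Axis 2: %.1f%% inertia\n",
                100 * fr[1], 100 * fr[2]))
  cat("  significant axes (> threshold): ",
      paste(x$significant_axes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot codon usage axes
#'
#' Axis 1 vs Axis 2 scatter of gene coordinates, optionally overlaying a
#' flagged subset (e.g. elevated-volatility or highly expressed genes) in a
#' paler colour.
#'
#' @param x a \code{usage_axes}.
#' @param overlay optional logical vector (length = genes) or character
#'   vector of gene ids to overlay.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.usage_axes <- function(x, overlay = NULL, ...) {
  tab <- x$table
  graphics::plot(tab$axis1, tab$axis2, pch = 16, cex = 0.5,
                 col = grDevices::grey(0.2),
                 xlab = "Axis 1", ylab = "Axis 2", ...)
  if (!is.null(overlay)) {
    sel <- if (is.character(overlay)) tab$gene_id %in% overlay else overlay
    graphics::points(tab$axis1[sel], tab$axis2[sel], pch = 16, cex = 0.6,
                     col = grDevices::grey(0.7))
  }
  invisible(x)
}
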