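# Correlation and overlay stage: volatility vs dN/dS, usage/volatility vs
# expression, and usage/volatility vs GC3.

#' Ordinary least-squares fit of y on x
#'
#' @param x,y equal-length finite numeric vectors (n >= 3); x must vary.
#' @return Object of class \code{regression_report}: \code{slope},
#'   \code{intercept}, \code{r_squared} (squared Pearson correlation; 0
#'   when y is constant), \code{n}.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 finite (x, y) pairs")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2, n = length(x)
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("y = %.4gx + %.4g   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Distribution overlay summary of a flagged subset
#'
#' Compares a flagged gene subset with its complement and with the full
#' set on one metric: means, SDs, and a rank-based two-sample location
#' test (Wilcoxon). Used to ask whether, e.g., elevated-volatility genes
#' sit anywhere unusual in the codon usage distribution. No
#' multiple-testing correction is applied at this layer.
#'
#' @param values numeric metric vector.
#' @param flags logical vector (same length); the subset must be non-empty.
#' @return Object of class \code{overlay_summary} with subset, complement
#'   and full mean/SD/n and the Wilcoxon \code{p_value} (NA when the
#'   complement is empty).
#' @export
overlay_summary <- function(values, flags) {
  stopifnot(length(values) == length(flags), is.logical(flags))
  ok <- is.finite(values) & !is.na(flags)
  values <- values[ok]; flags <- flags[ok]
  if (!any(flags)) stop("flagged subset is empty")
  st <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  p <- if (all(flags)) NA_real_ else
    suppressWarnings(stats::wilcox.test(values[flags], values[!flags])$p.value)
  structure(list(
    subset = st(values[flags]),
    complement = if (all(flags)) c(mean = NA, sd = NA, n = 0) else st(values[!flags]),
    full = st(values),
    p_value = p
  ), class = "overlay_summary")
}

#' @export
print.overlay_summary <- function(x, ...) {
  cat(sprintf("subset     : mean %.4g, sd %.4g (n = %d)\n",
              x$subset["mean"], x$subset["sd"], as.integer(x$subset["n"])))
  cat(sprintf("complement : mean %.4g, sd %.4g (n = %d)\n",
              x$complement["mean"], x$complement["sd"],
              as.integer(x$complement["n"])))
  cat(sprintf("full set   : mean %.4g, sd %.4g (n = %d)\n",
              x$full["mean"], x$full["sd"], as.integer(x$full["n"])))
  cat("rank-based location test P =", format(x$p_value), "\n")
  invisible(x)
}

#' Flag the most highly expressed genes
#'
#' Flags either the \code{top_n} genes or the top \code{top_fraction} of
#' genes by expression value; ties are broken by gene id so the flagging
#' is deterministic. The default fraction 0.167 mirrors flagging roughly
#' the top sixth of expressed genes.
#'
#' @param expression data frame with columns \code{gene_id} and a numeric
#'   expression column (first non-id column used), or a named numeric
#'   vector.
#' @param top_n number of genes to flag (overrides \code{top_fraction}).
#' @param top_fraction fraction of genes to flag.
#' @return Logical vector named by gene id, in the input order.
#' @export
select_high_expression <- function(expression, top_n = NULL,
                                   top_fraction = 0.167) {
  if (is.data.frame(expression)) {
    ids <- expression$gene_id
    vals <- expression[[setdiff(names(expression), "gene_id")[1]]]
  } else {
    ids <- names(expression); vals <- as.numeric(expression)
  }
  n <- length(vals)
  if (is.null(top_n)) top_n <- as.integer(round(top_fraction * n))
  if (top_n > n) stop("top_n (", top_n, ") exceeds table size (", n, ")")
  ord <- order(-vals, ids)
  flags <- logical(n)
  flags[ord[seq_len(top_n)]] <- TRUE
  stats::setNames(flags, ids)
}

.cor_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::var(x) == 0)
    return(NULL)
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  list(fit = fit_linear(x, y),
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Join pipeline stage outputs into one per-gene metric table
#'
#' Inner-joins the volatility scan, the usage axes, and optional expression
#' and dN/dS tables on gene id, adding elevated and high-expression flags.
#'
#' @param scan a \code{volatility_scan} (or its \code{results} data frame).
#' @param axes a \code{usage_axes} (or its \code{table} data frame).
#' @param expression optional data frame (gene_id, log2_expr).
#' @param dnds optional data frame with columns gene_id and omega.
#' @param high_expr_top_fraction fraction used for the high-expression
#'   flag when expression is given.
#' @param join \code{"pairwise"} (default) keeps every gene scored by both
#'   the scan and the usage stage and leaves NA where an optional metric
#'   (expression, omega) does not cover a gene, so each downstream
#'   comparison uses its own complete cases -- metrics like dN/dS
#'   inherently cover only an ortholog subset. \code{"inner"} restricts to
#'   genes present in every supplied metric.
#' @return Data frame with one row per gene.
#' @export
gene_metric_table <- function(scan, axes, expression = NULL, dnds = NULL,
                              high_expr_top_fraction = 0.167,
                              join = c("pairwise", "inner")) {
  join <- match.arg(join)
  all_x <- join == "pairwise"
  sdf <- if (inherits(scan, "volatility_scan")) scan$results else scan
  adf <- if (inherits(axes, "usage_axes")) axes$table else axes
  out <- merge(sdf[, c("gene_id", "v_sum", "v_mean", "p_value", "elevated_flag")],
               adf[, c("gene_id", "n_codons", "enc", "gc3", "axis1", "axis2")],
               by = "gene_id")
  if (!is.null(expression)) {
    flags <- select_high_expression(expression,
                                    top_fraction = high_expr_top_fraction)
    expression$high_expression_flag <- unname(flags)
    out <- merge(out, expression, by = "gene_id", all.x = all_x)
  }
  if (!is.null(dnds)) out <- merge(out, dnds[, c("gene_id", "omega")],
                                   by = "gene_id", all.x = all_x)
  out[order(out$gene_id), , drop = FALSE]
}

#' Association report across volatility, usage, expression, GC3 and dN/dS
#'
#' Quantifies the four headline comparisons on a joined gene metric table:
#' volatility P against dN/dS (omega), usage Axis 1 against expression,
#' volatility (P and per-codon mean) against GC3, and Axis 1 against GC3.
#' Each available comparison is reported as an OLS regression plus Pearson
#' and Spearman correlations with P-values (rank correlation is robust to
#' the heavy-tailed P-value scale); comparisons whose columns are missing
#' are skipped with a notice. Overlay summaries locate the
#' elevated-volatility and high-expression subsets on the usage axes.
#'
#' @param gmt data frame from [gene_metric_table()] (columns used when
#'   present: p_value, v_mean, axis1, axis2, gc3, log2_expr, omega,
#'   elevated_flag, high_expression_flag).
#' @return Object of class \code{association_report}: list with
#'   \code{comparisons} (named list of correlation/regression blocks),
#'   \code{overlays}, \code{skipped} (character vector of comparisons
#'   missing their inputs).
#' @export
association_report <- function(gmt) {
  pairs <- list(
    volatilityP_vs_omega = c("omega", "p_value"),
    axis1_vs_expression = c("log2_expr", "axis1"),
    volatilityP_vs_gc3 = c("gc3", "p_value"),
    v_mean_vs_gc3 = c("gc3", "v_mean"),
    axis1_vs_gc3 = c("gc3", "axis1")
  )
  comparisons <- list()
  skipped <- character(0)
  for (nm in names(pairs)) {
    cols <- pairs[[nm]]
    if (!all(cols %in% names(gmt))) {
      skipped <- c(skipped, nm)
      next
    }
    res <- .cor_pair(gmt[[cols[1]]], gmt[[cols[2]]])
    if (is.null(res)) skipped <- c(skipped, nm) else comparisons[[nm]] <- res
  }
  if (length(skipped))
    message("association_report: skipped (missing inputs): ",
            paste(skipped, collapse = ", "))
  overlays <- list()
  for (fl in c("elevated_flag", "high_expression_flag")) {
    if (!fl %in% names(gmt) || !any(gmt[[fl]], na.rm = TRUE)) next
    for (ax in c("axis1", "axis2")) {
      if (!ax %in% names(gmt)) next
      overlays[[paste(fl, ax, sep = "_on_")]] <-
        overlay_summary(gmt[[ax]], gmt[[fl]])
    }
  }
  structure(list(comparisons = comparisons, overlays = overlays,
                 skipped = skipped, n_genes = nrow(gmt)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Association report (", x$n_genes, " genes)\n", sep = "")
  for (nm in names(x$comparisons)) {
    cp <- x$comparisons[[nm]]
    cat(sprintf("  %-24s r = %+.3f (P = %.3g), rho = %+.3f (P = %.3g), R^2 = %.3f, n = %d\n",
                nm, cp$pearson_r, cp$pearson_p, cp$spearman_rho,
                cp$spearman_p, cp$fit$r_squared, cp$n))
  }
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  for (nm in names(x$overlays)) {
    ov <- x$overlays[[nm]]
    cat(sprintf("  overlay %-32s subset mean %+.3f vs full %+.3f (P = %.3g)\n",
                nm, ov$subset["mean"], ov$full["mean"], ov$p_value))
  }
  invisible(x)
}

#' Flatten an association report to a data frame
#'
#' @param x an \code{association_report}.
#' @param ... unused.
#' @return Data frame with one row per comparison.
#' @export
as.data.frame.association_report <- function(x, ...) {
  if (!length(x$comparisons))
    return(data.frame(comparison = character(0)))
  do.call(rbind, lapply(names(x$comparisons), function(nm) {
    cp <- x$comparisons[[nm]]
    data.frame(comparison = nm, slope = cp$fit$slope,
               intercept = cp$fit$intercept, r_squared = cp$fit$r_squared,
               pearson_r = cp$pearson_r, pearson_p = cp$pearson_p,
               spearman_rho = cp$spearman_rho, spearman_p = cp$spearman_p,
               n = cp$n, stringsAsFactors = FALSE)
  }))
}

#' Scatterplots of the headline comparisons
#'
#' Draws up to three panels: volatility P vs dN/dS, usage axes with
#' overlays, and Axis 1 vs GC3 with the fitted regression line.
#'
#' @param x an \code{association_report}.
#' @param gmt the gene metric table the report was built from.
#' @param ... unused.
#' @return \code{x}, invisibly.
#' @export
plot.association_report <- function(x, gmt, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (all(c("omega", "p_value") %in% names(gmt)))
    graphics::plot(gmt$omega, gmt$p_value, pch = 16, cex = 0.5,
                   xlab = "dN/dS", ylab = "volatility P",
                   main = "volatility vs dN/dS")
  if (all(c("axis1", "axis2") %in% names(gmt))) {
    graphics::plot(gmt$axis1, gmt$axis2, pch = 16, cex = 0.5,
                   col = grDevices::grey(0.2), xlab = "Axis 1",
                   ylab = "Axis 2", main = "codon usage axes")
    if ("elevated_flag" %in% names(gmt))
      graphics::points(gmt$axis1[gmt$elevated_flag],
                       gmt$axis2[gmt$elevated_flag],
                       pch = 16, cex = 0.6, col = grDevices::grey(0.7))
  }
  if (all(c("gc3", "axis1") %in% names(gmt))) {
    graphics::plot(gmt$gc3, gmt$axis1, pch = 16, cex = 0.5,
                   xlab = "GC3", ylab = "Axis 1", main = "usage vs GC3")
    if (!is.null(x$comparisons$axis1_vs_gc3))
      graphics::abline(x$comparisons$axis1_vs_gc3$fit$intercept,
                       x$comparisons$axis1_vs_gc3$fit$slope)
  }
  invisible(x)
}
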