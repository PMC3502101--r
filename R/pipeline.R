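# Orchestration: configuration handling and the end-to-end run that chains
# simulate -> volatility -> usage -> dnds -> associate, writing one TSV per
# stage plus a run manifest.

#' Default pipeline configuration
#'
#' The analysis constants default to the reference settings used throughout
#' the package: transition:transversion ratio kappa = 4.1, elevated
#' volatility threshold P < 1e-6, minimum gene length 100 bp,
#' high-expression fraction 0.167, significant-axis inertia cutoff 0.05.
#' The simulate stage parameters describe the synthetic genome to generate
#' when no FASTA input is supplied.
#'
#' @param ... named overrides of any default.
#' @return Object of class \code{run_config} (named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    kappa = 4.1,
    p_threshold = 1e-6,
    min_bp = 100,
    high_expr_fraction = 0.167,
    inertia_cutoff = 0.05,
    pvalue_method = "exact_normal",
    n_samples = 10000,
    seed = 1,
    # simulate stage
    n_genes = 200, min_codons = 100, max_codons = 400,
    gc3_bias = 0.5, gc3_sd = 0.08, selection_strength = 0,
    expression_mean = 6.44, expression_sd = 2.02,
    # dnds stage
    dnds_enabled = TRUE, dnds_n_pairs = 20, dnds_method = "M0",
    dnds_t = 0.5, dnds_kappa = 4.1,
    dnds_omega_meanlog = log(0.2), dnds_omega_sdlog = 0.5,
    dnds_coverage_fraction = 1.0,
    # optional external inputs
    fasta_path = "", expression_path = ""
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    if (kappa <= 0) stop("config: kappa must be positive")
    if (p_threshold <= 0 || p_threshold >= 1)
      stop("config: p_threshold must be in (0, 1)")
    if (min_bp < 0) stop("config: min_bp must be non-negative")
    if (high_expr_fraction <= 0 || high_expr_fraction > 1)
      stop("config: high_expr_fraction must be in (0, 1]")
    if (inertia_cutoff < 0 || inertia_cutoff >= 1)
      stop("config: inertia_cutoff must be in [0, 1)")
    if (!pvalue_method %in% c("exact_normal", "monte_carlo"))
      stop("config: unknown pvalue_method")
    if (!dnds_method %in% c("M0", "NG86"))
      stop("config: unknown dnds_method")
  })
  invisible(cfg)
}

#' Write / read a pipeline configuration file
#'
#' Flat \code{key = value} text format; numeric values are written with
#' full precision so a configuration round-trips losslessly.
#'
#' @param cfg a \code{run_config}.
#' @param path file path.
#' @return \code{path} (write) or the \code{run_config} (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  fmt <- vapply(cfg, function(v) {
    if (is.logical(v)) as.character(v)
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }, character(1))
  writeLines(paste(names(cfg), fmt, sep = " = "), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  base <- default_config()
  out <- as.list(base)
  unknown <- setdiff(keys, names(out))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (i in seq_along(keys)) {
    ref <- base[[keys[i]]]
    out[[keys[i]]] <- if (is.logical(ref)) as.logical(vals[i])
      else if (is.numeric(ref)) as.numeric(vals[i])
      else vals[i]
  }
  structure(out, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Chains the stages in dependency order: simulate (or load a FASTA),
#' validate, volatility scan, codon usage axes, ortholog-pair dN/dS, and
#' the association report. Every stage writes its TSV into \code{out_dir},
#' together with the resolved configuration and a run manifest; rejection
#' and filter counts are logged. A failure inside the dN/dS stage is
#' caught and logged, and the association report is built on the columns
#' that remain.
#'
#' When the configuration enables simulation (no \code{fasta_path}), the
#' per-gene dN/dS values come from ortholog pairs evolved from the
#' simulated genes under the one-ratio codon process with per-pair omega
#' drawn from a log-normal law, independent of every other gene property.
#'
#' @param cfg a \code{run_config} from [default_config()] /
#'   [read_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Object of class \code{pipeline_result}: list with \code{scan},
#'   \code{axes}, \code{dnds} (data frame or NULL), \code{metrics} (the
#'   joined gene metric table), \code{report}, \code{genome}, \code{files}.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("codvol_run_"),
                         quiet = FALSE) {
  validate_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[codvol] ", ...)
  files <- character(0)
  note <- function(p) { files <<- c(files, p); p }
  write_config(cfg, note(file.path(out_dir, "config_resolved.txt")))

  # --- simulate / load ---
  genome <- NULL
  if (nzchar(cfg$fasta_path)) {
    say("loading CDS FASTA from ", cfg$fasta_path)
    seqs <- read_fasta(cfg$fasta_path)
    expression <- if (nzchar(cfg$expression_path))
      read_tsv(cfg$expression_path) else NULL
  } else {
    say("simulating genome: ", cfg$n_genes, " genes (seed ", cfg$seed, ")")
    spec <- synthetic_genome_spec(
      n_genes = cfg$n_genes, min_codons = cfg$min_codons,
      max_codons = cfg$max_codons, gc3_bias = cfg$gc3_bias,
      gc3_sd = cfg$gc3_sd, selection_strength = cfg$selection_strength,
      expression_mean = cfg$expression_mean,
      expression_sd = cfg$expression_sd, seed = cfg$seed)
    genome <- generate_genome(spec)
    seqs <- genome$sequences
    expression <- genome$expression
    write_fasta(seqs, note(file.path(out_dir, "genome.fasta")))
    write_tsv(genome$truth, note(file.path(out_dir, "truth.tsv")))
    write_tsv(expression, note(file.path(out_dir, "expression.tsv")))
  }

  # --- validate ---
  vs <- validate_cds_set(seqs)
  say(length(vs$cds), " genes validated, ", nrow(vs$rejections), " rejected")
  write_tsv(vs$rejections, note(file.path(out_dir, "rejections.tsv")))
  if (length(vs$cds) < 3L) stop("fewer than 3 valid genes; cannot run pipeline")

  # --- volatility ---
  scan <- volatility_scan(vs$cds, model = mutation_model(cfg$kappa),
                          threshold = cfg$p_threshold,
                          method = cfg$pvalue_method,
                          n_samples = as.integer(cfg$n_samples),
                          seed = as.integer(cfg$seed) + 1L)
  say(sum(scan$results$elevated_flag), " genes elevated at P < ",
      format(cfg$p_threshold))
  write_tsv(scan$results, note(file.path(out_dir, "volatility.tsv")))

  # --- codon usage ---
  axes <- usage_axes(vs$cds, min_bp = cfg$min_bp,
                     significant_inertia = cfg$inertia_cutoff)
  say(nrow(axes$table), " genes in usage analysis, ",
      nrow(axes$excluded), " excluded by the ", cfg$min_bp, " bp filter")
  write_tsv(axes$table, note(file.path(out_dir, "usage.tsv")))
  ncol_ax <- ncol(axes$ca$column_coordinates)
  write_tsv(data.frame(
    codon = rownames(axes$ca$column_coordinates),
    mean_rscu = colMeans(axes$rscu_matrix[, rownames(axes$ca$column_coordinates),
                                          drop = FALSE], na.rm = TRUE),
    axis1 = if (ncol_ax >= 1) axes$ca$column_coordinates[, 1] else 0,
    axis2 = if (ncol_ax >= 2) axes$ca$column_coordinates[, 2] else 0,
    row.names = NULL
  ), note(file.path(out_dir, "rscu.tsv")))
  write_tsv(data.frame(axis = seq_along(axes$ca$inertia_fraction),
                       inertia_fraction = axes$ca$inertia_fraction,
                       significant = seq_along(axes$ca$inertia_fraction) %in%
                         axes$significant_axes),
            note(file.path(out_dir, "inertia.tsv")))

  # --- dN/dS on simulated ortholog pairs ---
  dnds_df <- NULL
  if (isTRUE(as.logical(cfg$dnds_enabled))) {
    dnds_df <- tryCatch({
      n_pairs <- min(as.integer(cfg$dnds_n_pairs), length(vs$cds))
      say("estimating dN/dS (", cfg$dnds_method, ") on ", n_pairs,
          " simulated ortholog pairs")
      pick <- .with_seed(as.integer(cfg$seed) + 2L,
                         sample(names(vs$cds), n_pairs))
      omegas <- .with_seed(as.integer(cfg$seed) + 3L,
        stats::rlnorm(n_pairs, cfg$dnds_omega_meanlog, cfg$dnds_omega_sdlog))
      rows <- vector("list", n_pairs)
      for (i in seq_len(n_pairs)) {
        cds1 <- vs$cds[[pick[i]]]
        pair <- evolve_pair(cds1, ortholog_sim_spec(
          omega = omegas[i], kappa = cfg$dnds_kappa, t = cfg$dnds_t,
          freq_model = "F61", seed = as.integer(cfg$seed) + 10L + i))
        ortho <- pair$derived
        if (cfg$dnds_coverage_fraction < 1)
          ortho <- truncate_to_fragment(ortho, cfg$dnds_coverage_fraction,
                                        seed = as.integer(cfg$seed) + 5000L + i)
        est <- dnds_pair(cds1, ortho, method = cfg$dnds_method)
        rows[[i]] <- data.frame(
          gene_id = pick[i], method = est$method, dN = est$dN, dS = est$dS,
          omega = est$omega, kappa_hat = est$kappa_hat, t_hat = est$t_hat,
          lnL = if (is.null(est$logLik)) NA_real_ else est$logLik,
          true_omega = omegas[i], coverage_pct = est$coverage_pct,
          flag = est$flag, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }, error = function(e) {
      say("dN/dS stage failed (", conditionMessage(e),
          "); association will skip the omega comparison")
      NULL
    })
  } else say("dN/dS stage disabled; association will skip the omega comparison")
  if (!is.null(dnds_df))
    write_tsv(dnds_df, note(file.path(out_dir, "dnds.tsv")))

  # --- association ---
  gmt <- gene_metric_table(scan, axes, expression = expression,
                           dnds = dnds_df,
                           high_expr_top_fraction = cfg$high_expr_fraction)
  report <- suppressMessages(association_report(gmt))
  write_tsv(as.data.frame(report), note(file.path(out_dir, "association.tsv")))
  write_tsv(gmt, note(file.path(out_dir, "gene_metrics.tsv")))

  manifest <- data.frame(
    key = c("package_version", "seed", "n_input_genes", "n_valid_genes",
            "n_rejected", "n_elevated", "n_usage_genes", "n_dnds_pairs",
            "files"),
    value = c(as.character(utils::packageVersion("codvol")), cfg$seed,
              length(seqs), length(vs$cds), nrow(vs$rejections),
              sum(scan$results$elevated_flag), nrow(axes$table),
              if (is.null(dnds_df)) 0L else nrow(dnds_df),
              paste(basename(files), collapse = ";")),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  files <- c(files, file.path(out_dir, "manifest.tsv"))

  structure(list(scan = scan, axes = axes, dnds = dnds_df, metrics = gmt,
                 report = report, genome = genome, out_dir = out_dir,
                 files = files, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("codvol pipeline run -> ", x$out_dir, "\n", sep = "")
  print(x$scan)
  print(x$axes)
  if (!is.null(x$dnds))
    cat("dN/dS pairs estimated: ", nrow(x$dnds), " (",
        x$dnds$method[1], ")\n", sep = "")
  print(x$report)
  invisible(x)
}
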