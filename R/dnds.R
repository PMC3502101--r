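# Protein-guided pairwise codon alignment and dN/dS estimation:
# Nei-Gojobori (1986) counting and maximum likelihood under the one-ratio
# (M0) Goldman-Yang-style codon substitution model.

# ---- codon substitution model machinery (shared with the simulator) ----

.codvol_cache <- new.env(parent = emptyenv())

# Single-nucleotide-change graph over the 61 sense codons: for each ordered
# neighbouring pair, whether the change is a transition and whether it is
# synonymous.
.codon_graph <- function(code = standard_genetic_code()) {
  key <- paste(code$sense_codons, collapse = "")
  if (!is.null(.codvol_cache[[key]])) return(.codvol_cache[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  ts <- syn <- adj <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  split3 <- strsplit(sense, "")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diffpos <- which(split3[[i]] != split3[[j]])
    if (length(diffpos) != 1L) next
    adj[i, j] <- TRUE
    ts[i, j] <- mutation_class(split3[[i]][diffpos], split3[[j]][diffpos]) == "transition"
    syn[i, j] <- code$codon_to_aa[[sense[i]]] == code$codon_to_aa[[sense[j]]]
  }
  g <- list(sense = sense, adj = adj, ts = ts, syn = syn)
  .codvol_cache[[key]] <- g
  g
}

#' Equilibrium codon frequencies for the codon model
#'
#' @param codons character vector of sense codons observed (both sequences
#'   pooled), used by the empirical models; ignored by \code{"uniform"}.
#' @param model \code{"F3x4"} (position-specific nucleotide frequencies,
#'   the default of the M0 fit), \code{"F61"} (empirical codon frequencies
#'   with a small floor so no sense codon has probability 0), or
#'   \code{"uniform"}.
#' @param code a \code{genetic_code}.
#' @return Named probability vector over the 61 sense codons.
#' @export
codon_equilibrium_freqs <- function(codons,
                                    model = c("F3x4", "F61", "uniform"),
                                    code = standard_genetic_code()) {
  model <- match.arg(model)
  sense <- code$sense_codons
  if (model == "uniform") {
    pi <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
    return(pi)
  }
  codons <- codons[codons %in% sense]
  if (length(codons) == 0L) stop("no sense codons supplied")
  if (model == "F61") {
    n <- table(factor(codons, levels = sense))
    pi <- (as.numeric(n) + 0.5) / sum(as.numeric(n) + 0.5)
  } else {
    # F3x4: product of per-position nucleotide frequencies, stops removed
    pos_freq <- lapply(1:3, function(p) {
      tb <- table(factor(substr(codons, p, p), levels = .BASES))
      (as.numeric(tb) + 0.25) / sum(as.numeric(tb) + 0.25)
    })
    pi <- vapply(sense, function(cd) {
      prod(vapply(1:3, function(p)
        pos_freq[[p]][match(substr(cd, p, p), .BASES)], numeric(1)))
    }, numeric(1))
    pi <- pi / sum(pi)
  }
  stats::setNames(pi, sense)
}

# Rate matrix of the one-ratio codon model: q_ij proportional to
# pi_j * kappa^[transition] * omega^[nonsynonymous] for single-nucleotide
# changes, 0 otherwise; scaled so the expected substitution rate at
# equilibrium is 1 per codon per unit time.
.codon_Q <- function(pi, kappa, omega, code = standard_genetic_code(),
                     normalize = TRUE) {
  g <- .codon_graph(code)
  n <- length(g$sense)
  S <- matrix(0, n, n, dimnames = list(g$sense, g$sense))
  S[g$adj] <- 1
  S[g$adj & g$ts] <- kappa
  S[g$adj & !g$syn] <- S[g$adj & !g$syn] * omega
  Q <- S * rep(pi[g$sense], each = n)
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(pi[g$sense] * diag(Q))
    Q <- Q / rate
  }
  Q
}

# Transition probability matrix exp(Qt) via the reversible symmetrization
# D^{1/2} Q D^{-1/2}; exact for this model because kappa/omega factors are
# symmetric in i,j.
.codon_P <- function(pi, kappa, omega, t, code = standard_genetic_code()) {
  Q <- .codon_Q(pi, kappa, omega, code)
  d <- sqrt(pi[rownames(Q)])
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * ((1 / d) %o% d)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- alignment ----

#' Align two protein sequences
#'
#' Optimal dynamic-programming alignment (Smith-Waterman local, the default
#' for partial orthologs, or Needleman-Wunsch global), delegated to
#' \code{Biostrings::pairwiseAlignment} with BLOSUM62 scoring and affine
#' gap penalties.
#'
#' @param p1,p2 amino-acid strings.
#' @param substitution_matrix scoring matrix name or matrix (default
#'   "BLOSUM62", shipped with Biostrings).
#' @param gap_open,gap_extend positive gap penalties (defaults 11 and 1).
#' @param mode \code{"local"} or \code{"global"}.
#' @return Object of class \code{protein_alignment}: list with
#'   \code{aligned1}, \code{aligned2} (equal-length gapped strings),
#'   \code{score}, \code{mode}, \code{start1}, \code{start2} (1-based
#'   residue offsets of the aligned block in each input).
#' @export
align_proteins <- function(p1, p2, substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(p1) || !nzchar(p2)) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = mode, substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(
    aligned1 = as.character(Biostrings::alignedPattern(pa)),
    aligned2 = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa), mode = mode,
    start1 = Biostrings::start(Biostrings::pattern(pa)),
    start2 = Biostrings::start(Biostrings::subject(pa))
  ), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> (", x$mode, "), score ", x$score, ", length ",
      nchar(x$aligned1), "\n", sep = "")
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Uses a gapped protein alignment as a guide to align the two coding
#' sequences codon-by-codon: each residue column maps to the residue's
#' source codon, each protein gap to a whole-codon gap, so the alignment
#' never breaks frame.
#'
#' @param pa a \code{protein_alignment} of the two translation products.
#' @param cds1,cds2 the validated \code{cds} objects the proteins came from.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{codon_alignment}: list with \code{codons1},
#'   \code{codons2} (equal-length codon vectors, gaps as \code{"---"}),
#'   \code{gene_ids}, \code{ref_codons} (full codon counts of the two CDS).
#' @export
backtranslate_alignment <- function(pa, cds1, cds2,
                                    code = standard_genetic_code()) {
  a1 <- strsplit(pa$aligned1, "")[[1]]
  a2 <- strsplit(pa$aligned2, "")[[1]]
  stopifnot(length(a1) == length(a2))
  take <- function(aligned, cds, start, which) {
    out <- character(length(aligned))
    ptr <- start
    for (k in seq_along(aligned)) {
      if (aligned[k] == "-") {
        out[k] <- "---"
      } else {
        cod <- cds$codons[ptr]
        if (is.na(cod) || code$codon_to_aa[[cod]] != aligned[k])
          stop("translation mismatch in sequence ", which,
               " at aligned residue ", k, " (codon index ", ptr, "): codon ",
               cod, " does not encode ", aligned[k])
        out[k] <- cod
        ptr <- ptr + 1L
      }
    }
    out
  }
  structure(list(
    codons1 = take(a1, cds1, pa$start1, 1L),
    codons2 = take(a2, cds2, pa$start2, 2L),
    gene_ids = c(cds1$gene_id, cds2$gene_id),
    ref_codons = c(length(cds1$codons), length(cds2$codons))
  ), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  ung <- sum(x$codons1 != "---" & x$codons2 != "---")
  cat("<codon_alignment> ", x$gene_ids[1], " / ", x$gene_ids[2], ": ",
      length(x$codons1), " columns, ", ung, " ungapped codon pairs\n", sep = "")
  invisible(x)
}

#' Alignment coverage of a reference CDS
#'
#' Percentage of the reference coding sequence covered by ungapped aligned
#' codon pairs; used to report how much of a gene a partial ortholog
#' fragment spans.
#'
#' @param ca a \code{codon_alignment}.
#' @param reference which sequence (1 or 2) is the reference.
#' @return Percentage in (0, 100].
#' @export
alignment_coverage <- function(ca, reference = 1L) {
  stopifnot(reference %in% c(1L, 2L))
  ref_n <- ca$ref_codons[reference]
  if (ref_n <= 0) stop("reference length must be positive")
  100 * sum(ca$codons1 != "---" & ca$codons2 != "---") / ref_n
}

# ---- NG86 counting estimator ----

# Per-codon synonymous site count: at each position the fraction of the
# three possible changes that is synonymous, mutations creating stop codons
# excluded from both numerator and denominator; each position contributes
# one site.
.ng86_sites <- function(codon, code) {
  chars <- strsplit(codon, "")[[1]]
  aa <- code$codon_to_aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- nonstop <- 0L
    for (b in setdiff(.BASES, chars[pos])) {
      nb <- chars; nb[pos] <- b
      nb_aa <- code$codon_to_aa[[paste(nb, collapse = "")]]
      if (nb_aa == "*") next
      nonstop <- nonstop + 1L
      if (nb_aa == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  s
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all minimal mutational pathways, pathways passing through stop
# codons excluded (all-blocked pairs fall back to averaging over every
# pathway).
.ng86_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  paths <- if (d == 1L) list(pos) else {
    perms <- if (d == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) pos[o])
    }
    perms
  }
  target <- strsplit(c2, "")[[1]]
  walk <- function(order) {
    cur <- strsplit(c1, "")[[1]]
    sd <- nd <- 0
    for (p in order) {
      prev_aa <- code$codon_to_aa[[paste(cur, collapse = "")]]
      cur[p] <- target[p]
      nxt <- paste(cur, collapse = "")
      nxt_aa <- code$codon_to_aa[[nxt]]
      if (nxt_aa == "*") return(NULL)
      if (nxt_aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk))
  if (length(res) == 0L) {
    # every minimal pathway traverses a stop: count steps ignoring stops
    walk_any <- function(order) {
      cur <- strsplit(c1, "")[[1]]
      sd <- nd <- 0
      for (p in order) {
        prev_aa <- code$codon_to_aa[[paste(cur, collapse = "")]]
        cur[p] <- target[p]
        nxt_aa <- code$codon_to_aa[[paste(cur, collapse = "")]]
        if (nxt_aa == prev_aa && nxt_aa != "*") sd <- sd + 1 else nd <- nd + 1
      }
      c(sd = sd, nd = nd)
    }
    res <- lapply(paths, walk_any)
  }
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori (1986) dN/dS
#'
#' Counting estimator of synonymous and nonsynonymous divergence on a codon
#' alignment: site counts are averaged over the two sequences, multi-hit
#' codon pairs are averaged over all minimal mutational pathways (pathways
#' through stop codons excluded), and the Jukes-Cantor correction is
#' applied to the proportions. Gapped columns are dropped (pairwise
#' deletion). The estimate is symmetric in sequence order.
#'
#' @param ca a \code{codon_alignment} with >= 1 ungapped codon pair.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{dnds_estimate}: dN, dS, omega (NA when
#'   dS = 0), site and difference counts, proportions, method tag
#'   \code{"NG86"}, and a \code{flag} (\code{"ok"}, or
#'   \code{"saturated"} when a proportion reaches the Jukes-Cantor limit
#'   of 3/4 and the corrected distance is undefined).
#' @export
ng86_dnds <- function(ca, code = standard_genetic_code()) {
  keep <- ca$codons1 != "---" & ca$codons2 != "---"
  c1 <- ca$codons1[keep]; c2 <- ca$codons2[keep]
  if (length(c1) == 0L) stop("no ungapped codon pairs")
  site_tab <- vapply(unique(c(c1, c2)), .ng86_sites, numeric(1), code = code)
  S <- (sum(site_tab[c1]) + sum(site_tab[c2])) / 2
  N <- 3 * length(c1) - S
  sd_tot <- nd_tot <- 0
  for (k in seq_along(c1)) {
    if (c1[k] == c2[k]) next
    dd <- .ng86_diffs(c1[k], c2[k], code)
    sd_tot <- sd_tot + dd["sd"]
    nd_tot <- nd_tot + dd["nd"]
  }
  pS <- sd_tot / S
  pN <- nd_tot / N
  jc <- function(p) if (p >= 3/4) NA_real_ else -3/4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  flag <- if (is.na(dS) || is.na(dN)) "saturated" else "ok"
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(
    dN = unname(dN), dS = unname(dS), omega = unname(omega),
    kappa_hat = NA_real_, t_hat = NA_real_,
    S = unname(S), N = unname(N), Sd = unname(sd_tot), Nd = unname(nd_tot),
    pS = unname(pS), pN = unname(pN),
    method = "NG86", flag = flag, gene_ids = ca$gene_ids,
    n_codon_pairs = length(c1)
  ), class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat("<dnds_estimate> [", x$method, "] ",
      paste(x$gene_ids, collapse = " / "), "\n", sep = "")
  cat(sprintf("  dN = %.4f, dS = %.4f, dN/dS = %s",
              x$dN, x$dS, ifelse(is.na(x$omega), "undefined",
                                 sprintf("%.4f", x$omega))))
  if (!is.na(x$kappa_hat))
    cat(sprintf(", kappa = %.2f, t = %.3f", x$kappa_hat, x$t_hat))
  cat("  [", x$flag, "]\n", sep = "")
  invisible(x)
}

# ---- M0 maximum-likelihood estimator ----

#' Fit the one-ratio (M0) codon model to a pairwise alignment
#'
#' Maximum-likelihood estimation of (t, kappa, omega) under the 61-state
#' codon substitution model in which the instantaneous rate from codon i to
#' codon j is proportional to pi_j, multiplied by kappa for transitions and
#' by omega for nonsynonymous changes, and zero for multi-nucleotide
#' changes. The likelihood is the product over ungapped codon columns of
#' pi_i * P_ij(t). Optimization is bounded quasi-Newton (L-BFGS-B on log
#' parameters) from three starting omegas (0.1, 0.5, 2.0), converged at an
#' absolute log-likelihood tolerance near 1e-8. dN and dS are derived from
#' the fitted process by the standard rate decomposition (expected
#' synonymous/nonsynonymous substitutions over the fitted time, divided by
#' the corresponding site fractions computed at omega = 1), under which
#' dN/dS equals the fitted omega.
#'
#' @param ca a \code{codon_alignment}; at least 50 ungapped codon pairs are
#'   recommended (a warning is issued below that).
#' @param freq_model equilibrium frequency model, see
#'   [codon_equilibrium_freqs()]; default \code{"F3x4"}.
#' @param starts numeric vector of starting omega values.
#' @param code a \code{genetic_code}.
#' @return Object of class \code{m0_fit} (also \code{dnds_estimate}): dN,
#'   dS, omega, kappa_hat, t_hat, logLik, convergence flag, frequency
#'   model tag, and the codon-pair count. \code{coef()} returns
#'   (t, kappa, omega); \code{logLik()} the maximized log-likelihood.
#' @export
m0_fit <- function(ca, freq_model = c("F3x4", "F61", "uniform"),
                   starts = c(0.1, 0.5, 2.0),
                   code = standard_genetic_code()) {
  freq_model <- match.arg(freq_model)
  keep <- ca$codons1 != "---" & ca$codons2 != "---"
  c1 <- ca$codons1[keep]; c2 <- ca$codons2[keep]
  npairs <- length(c1)
  if (npairs == 0L) stop("no ungapped codon pairs")
  if (npairs < 50L)
    warning("only ", npairs, " ungapped codon pairs; M0 estimates will be noisy")
  sense <- code$sense_codons
  pi <- codon_equilibrium_freqs(c(c1, c2), model = freq_model, code = code)
  i1 <- factor(c1, levels = sense)
  i2 <- factor(c2, levels = sense)
  counts <- table(i1, i2)
  cn <- as.matrix(counts)
  nonzero <- which(cn > 0, arr.ind = TRUE)
  nvec <- cn[nonzero]
  negll <- function(logpar) {
    t <- exp(logpar[1]); kap <- exp(logpar[2]); om <- exp(logpar[3])
    P <- .codon_P(pi, kap, om, t, code)
    lik <- pi[nonzero[, 1]] * P[nonzero]
    lik[lik < 1e-300] <- 1e-300
    -sum(nvec * log(lik))
  }
  pdiff <- mean(c1 != c2)
  t0 <- max(0.02, -log(max(1 - pdiff * 61 / 60, 0.02)))
  lower <- log(c(1e-6, 1e-2, 1e-4))
  upper <- log(c(50, 100, 50))
  best <- NULL
  conv <- FALSE
  for (om0 in starts) {
    fit <- try(stats::optim(log(c(t0, 2, om0)), negll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e5, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- conv || fit$convergence == 0
    } else if (fit$convergence == 0 && fit$value <= best$value + 1e-6) {
      conv <- TRUE
    }
  }
  if (is.null(best)) stop("M0 optimization failed from every start")
  par <- exp(best$par)
  t_hat <- par[1]; kappa_hat <- par[2]; omega_hat <- par[3]
  # rate decomposition: expected syn/nonsyn flux of the fitted (normalized)
  # process, and site fractions from the omega = 1 mutational opportunity
  g <- .codon_graph(code)
  flux <- function(om) {
    Q <- .codon_Q(pi, kappa_hat, om, code, normalize = FALSE)
    qs <- sum(pi[g$sense] * rowSums(Q * (g$adj & g$syn)))
    qn <- sum(pi[g$sense] * rowSums(Q * (g$adj & !g$syn)))
    c(qs, qn)
  }
  f_fit <- flux(omega_hat)
  rho <- f_fit / sum(f_fit)                 # fitted per-unit-time proportions
  f1 <- flux(1)
  pS1 <- f1[1] / sum(f1)                    # synonymous site fraction
  dS <- t_hat * rho[1] / (3 * pS1)
  dN <- t_hat * rho[2] / (3 * (1 - pS1))
  structure(list(
    dN = dN, dS = dS, omega = omega_hat, kappa_hat = kappa_hat, t_hat = t_hat,
    logLik = -best$value, converged = conv, freq_model = freq_model,
    method = "M0", flag = if (conv) "ok" else "not_converged",
    gene_ids = ca$gene_ids, n_codon_pairs = npairs, pi = pi
  ), class = c("m0_fit", "dnds_estimate"))
}

#' @export
coef.m0_fit <- function(object, ...) {
  c(t = object$t_hat, kappa = object$kappa_hat, omega = object$omega)
}

#' @export
logLik.m0_fit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n_codon_pairs,
            class = "logLik")
}

#' Log-likelihood of a codon alignment under given M0 parameters
#'
#' Evaluates the one-ratio codon model likelihood at a fixed parameter
#' point (no optimization); useful for checking that a fitted optimum is
#' at least as good as the generating parameters of a simulation.
#'
#' @param ca a \code{codon_alignment}.
#' @param t,kappa,omega model parameters.
#' @param freq_model equilibrium frequency model.
#' @param code a \code{genetic_code}.
#' @return Log-likelihood (scalar).
#' @export
m0_loglik <- function(ca, t, kappa, omega, freq_model = "F3x4",
                      code = standard_genetic_code()) {
  keep <- ca$codons1 != "---" & ca$codons2 != "---"
  c1 <- ca$codons1[keep]; c2 <- ca$codons2[keep]
  pi <- codon_equilibrium_freqs(c(c1, c2), model = freq_model, code = code)
  P <- .codon_P(pi, kappa, omega, t, code)
  lik <- pi[c1] * P[cbind(c1, c2)]
  lik[lik < 1e-300] <- 1e-300
  sum(log(lik))
}

#' Pairwise dN/dS from two coding sequences
#'
#' Convenience chain for ortholog pairs: translate, align the proteins,
#' back-translate to a codon alignment, and estimate dN/dS by the requested
#' method, reporting coverage of the first (reference) CDS.
#'
#' @param cds1,cds2 validated \code{cds} objects (cds1 is the reference for
#'   coverage).
#' @param method \code{"NG86"} or \code{"M0"}.
#' @param mode protein alignment mode (default local, for partial
#'   fragments).
#' @param ... passed to [m0_fit()].
#' @param code a \code{genetic_code}.
#' @return The \code{dnds_estimate}, with \code{coverage_pct} added.
#' @export
dnds_pair <- function(cds1, cds2, method = c("M0", "NG86"),
                      mode = c("local", "global"), ...,
                      code = standard_genetic_code()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  pa <- align_proteins(translate_cds(cds1, code), translate_cds(cds2, code),
                       mode = mode)
  ca <- backtranslate_alignment(pa, cds1, cds2, code)
  est <- if (method == "NG86") ng86_dnds(ca, code) else m0_fit(ca, code = code, ...)
  est$coverage_pct <- alignment_coverage(ca, reference = 1L)
  est
}
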