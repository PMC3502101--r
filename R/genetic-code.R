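#' The standard nuclear genetic code
#'
#' Returns the standard genetic code (NCBI translation table 1) as used by
#' all codon arithmetic in the package: a mapping of the 64 codons
#' (alphabet ACGT) to one-letter amino-acid symbols, with stop codons coded
#' as \code{"*"}, plus the set of synonymously degenerate codons.
#'
#' The degenerate set contains the 59 sense codons that have at least one
#' synonymous alternative, i.e. all sense codons except the single-codon
#' families ATG (Met) and TGG (Trp). Only this set enters RSCU, GC3 and the
#' correspondence-analysis space.
#'
#' The code table is an explicit argument of the lower-level functions so
#' that toy codes can be substituted in tests; only the standard nuclear
#' code ships with the package.
#'
#' @return An object of class \code{genetic_code}: a list with elements
#'   \item{codon_to_aa}{named character vector of length 64; stops are \code{"*"}.}
#'   \item{sense_codons}{the 61 non-stop codons.}
#'   \item{stop_codons}{the 3 stop codons.}
#'   \item{degenerate_codons}{the 59 codons with a synonymous alternative.}
#'   \item{families}{list mapping each amino-acid symbol to its codons.}
#' @examples
#' gc <- standard_genetic_code()
#' length(gc$degenerate_codons)  # 59
#' @export
standard_genetic_code <- function() {
  map <- Biostrings::GENETIC_CODE
  codons <- names(map)
  # Biostrings uses T already; enforce ACGT ordering by position for determinism
  stopifnot(length(map) == 64L)
  stops <- codons[map == "*"]
  sense <- codons[map != "*"]
  fam <- split(sense, map[sense])
  fam_size <- vapply(fam, length, integer(1))
  degenerate <- sort(unlist(fam[fam_size > 1L], use.names = FALSE))
  structure(list(
    codon_to_aa = map,
    sense_codons = sense,
    stop_codons = stops,
    degenerate_codons = degenerate,
    families = fam
  ), class = "genetic_code")
}

#' Transition/transversion mutation model
#'
#' Holds the transition:transversion weighting kappa used when codon
#' volatility counts mutational neighbours. \code{kappa = 1} recovers plain
#' unweighted counting; the genome-scan default elsewhere in the package is
#' \code{kappa = 4.1}.
#'
#' @param kappa positive real; weight given to transitions relative to
#'   transversions.
#' @return An object of class \code{mutation_model}.
#' @export
mutation_model <- function(kappa = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a single positive finite number")
  structure(list(kappa = as.numeric(kappa)), class = "mutation_model")
}

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

#' Classify a point mutation as transition or transversion
#'
#' @param base_from,base_to distinct single nucleotides in ACGT.
#' @return \code{"transition"} (purine-purine or pyrimidine-pyrimidine) or
#'   \code{"transversion"}.
#' @examples
#' mutation_class("A", "G")  # transition
#' mutation_class("A", "C")  # transversion
#' @export
mutation_class <- function(base_from, base_to) {
  if (!base_from %in% .BASES || !base_to %in% .BASES)
    stop("bases must be one of A, C, G, T")
  if (base_from == base_to)
    stop("bases must differ: a non-mutation has no class")
  if ((base_from %in% .PURINES) == (base_to %in% .PURINES)) "transition" else "transversion"
}

.check_codon <- function(codon, code) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stop("invalid codon '", codon, "': must be 3 letters over ACGT")
  if (code$codon_to_aa[[codon]] == "*")
    stop("stop codon '", codon, "' is not a valid input")
  invisible(codon)
}

#' Enumerate single-point-mutation neighbours of a codon
#'
#' Lists every codon reachable from \code{codon} by one nucleotide change,
#' excluding neighbours that are stop codons (stop codons are disallowed as
#' mutational neighbours throughout the volatility calculation).
#'
#' @param codon a sense codon (3 letters over ACGT).
#' @param code a \code{genetic_code}, see [standard_genetic_code()].
#' @return A data frame with one row per non-stop neighbour and columns
#'   \code{neighbor}, \code{position} (1-3), \code{class}
#'   (transition/transversion), \code{synonymous} (logical).
#' @examples
#' nrow(point_mutation_neighbors("AGA"))  # 8: TGA removed as stop
#' @export
point_mutation_neighbors <- function(codon, code = standard_genetic_code()) {
  .check_codon(codon, code)
  aa <- code$codon_to_aa[[codon]]
  chars <- strsplit(codon, "")[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (b in setdiff(.BASES, chars[pos])) {
      nb <- chars
      nb[pos] <- b
      nb <- paste(nb, collapse = "")
      nb_aa <- code$codon_to_aa[[nb]]
      if (nb_aa == "*") next
      k <- k + 1L
      out[[k]] <- data.frame(
        neighbor = nb, position = pos,
        class = mutation_class(chars[pos], b),
        synonymous = identical(nb_aa, aa),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Codon volatility
#'
#' The volatility of a sense codon is the probability that a random point
#' mutation (weighted by the transition:transversion ratio kappa) produces a
#' nonsynonymous change, neighbours that are stop codons being excluded from
#' both numerator and denominator. For AGA with kappa = 1 this is 6/8: of
#' the eight non-stop single-mutation neighbours, six encode an amino acid
#' other than arginine.
#'
#' @inheritParams point_mutation_neighbors
#' @param model a \code{mutation_model}; transitions receive weight
#'   \code{model$kappa}, transversions weight 1.
#' @return A number in [0, 1]; exactly 1 for the single-codon families ATG
#'   and TGG.
#' @examples
#' codon_volatility("AGA")                        # 6/8
#' codon_volatility("AGA", model = mutation_model(4.1))
#' @export
codon_volatility <- function(codon, code = standard_genetic_code(),
                             model = mutation_model(1)) {
  nb <- point_mutation_neighbors(codon, code)
  if (is.null(nb) || nrow(nb) == 0L)
    stop("codon '", codon, "' has no non-stop neighbors; impossible in the standard code")
  w <- ifelse(nb$class == "transition", model$kappa, 1)
  sum(w[!nb$synonymous]) / sum(w)
}

#' Volatility of every sense codon
#'
#' Convenience table used by the gene-level functions: volatility of all
#' sense codons under a given mutation model.
#'
#' @inheritParams codon_volatility
#' @return Named numeric vector over the 61 sense codons.
#' @export
volatility_table <- function(code = standard_genetic_code(),
                             model = mutation_model(1)) {
  key <- paste0("vt_", paste(code$sense_codons, collapse = ""), "_", model$kappa)
  cached <- get0(key, envir = .codvol_cache)
  if (!is.null(cached)) return(cached)
  vt <- vapply(code$sense_codons, codon_volatility, numeric(1),
               code = code, model = model)
  assign(key, vt, envir = .codvol_cache)
  vt
}
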