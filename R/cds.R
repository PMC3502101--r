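#' Validate a raw coding sequence
#'
#' Turns a raw nucleotide string into a codon-partitioned coding sequence,
#' or a typed rejection record. A single trailing stop codon is stripped
#' silently; a sequence is rejected (never silently repaired) when its
#' length is not divisible by 3, when it contains ambiguity characters, or
#' when a stop codon occurs internally.
#'
#' @param sequence nucleotide string (case-insensitive; U is accepted and
#'   converted to T).
#' @param gene_id identifier carried through the pipeline.
#' @param code a \code{genetic_code}.
#' @param source_note free-text provenance note.
#' @return An object of class \code{cds} (list with \code{gene_id},
#'   \code{codons}, \code{source_note}) or of class \code{cds_rejection}
#'   (list with \code{gene_id}, \code{reason}).
#' @examples
#' validate_cds("ATGAAATGA", "g1")$codons  # ATG AAA; trailing TGA stripped
#' validate_cds("ATGTGAAAA", "g2")         # rejected: internal stop
#' @export
validate_cds <- function(sequence, gene_id, code = standard_genetic_code(),
                         source_note = "") {
  reject <- function(reason) structure(
    list(gene_id = gene_id, reason = reason), class = "cds_rejection")
  s <- toupper(gsub("\\s", "", sequence))
  s <- chartr("U", "T", s)
  n <- nchar(s)
  if (n == 0L) return(reject("empty_sequence"))
  if (n %% 3L != 0L) return(reject("length_not_multiple_of_3"))
  if (grepl("[^ACGT]", s)) return(reject("ambiguity_characters"))
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- code$codon_to_aa[codons]
  if (aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (length(codons) == 0L) return(reject("empty_after_stop_strip"))
  if (any(aa == "*")) return(reject("internal_stop"))
  structure(list(gene_id = gene_id, codons = codons, source_note = source_note),
            class = "cds")
}

#' @export
print.cds <- function(x, ...) {
  cat("<cds> ", x$gene_id, ": ", length(x$codons), " codons (",
      3L * length(x$codons), " bp)\n", sep = "")
  invisible(x)
}

is_cds <- function(x) inherits(x, "cds")

#' Validate a set of raw sequences
#'
#' @param sequences named character vector of raw nucleotide strings.
#' @param code a \code{genetic_code}.
#' @return List with \code{cds} (list of validated \code{cds} objects, named
#'   by gene id) and \code{rejections} (data frame gene_id/reason; zero rows
#'   when nothing was rejected).
#' @export
validate_cds_set <- function(sequences, code = standard_genetic_code()) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop("'sequences' must be a named vector of nucleotide strings")
  res <- lapply(names(sequences), function(id)
    validate_cds(sequences[[id]], id, code))
  ok <- vapply(res, is_cds, logical(1))
  rej <- res[!ok]
  list(
    cds = stats::setNames(res[ok], vapply(res[ok], `[[`, "", "gene_id")),
    rejections = data.frame(
      gene_id = vapply(rej, `[[`, "", "gene_id"),
      reason = vapply(rej, `[[`, "", "reason"),
      stringsAsFactors = FALSE
    )
  )
}

#' Translate a coding sequence
#'
#' @param cds a validated \code{cds}.
#' @param code a \code{genetic_code}.
#' @return Single amino-acid string.
#' @export
translate_cds <- function(cds, code = standard_genetic_code()) {
  stopifnot(is_cds(cds))
  paste(code$codon_to_aa[cds$codons], collapse = "")
}

#' Read a multi-FASTA file of sequences
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that tolerates
#' wrapped lines and CRLF endings, truncates record ids at the first
#' whitespace, errors on duplicated ids, and warns on an empty file.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "))
  seqs
}

#' Write sequences to a multi-FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Write a data frame as a TSV file
#'
#' UTF-8, header row, newline-terminated; the format used by every pipeline
#' stage output.
#'
#' @param df data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#' @param path file path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
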