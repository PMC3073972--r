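#' Round half away from zero
#'
#' Printed tables in bioassay and sequencing reports round 0.005 up, not to
#' even as [base::round()] does. Used only at the reporting layer; internal
#' arithmetic keeps full precision.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up (half-down for negatives).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# run expr with a private RNG stream; caller's .Random.seed untouched
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a unigene FASTA file
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_unigene_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  # FASTA headers may carry descriptions; the id is the first word
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_unigene_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a raw tag library (one tag per line, or FASTQ)
#'
#' Lines starting with `@`/`+` trigger FASTQ interpretation, in which case
#' only the sequence field of each 4-line record is kept.
#'
#' @param path path to the tag file.
#' @return character vector of uppercase tag observations.
#' @export
read_tag_library <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[[1]], "@")) {
    if (length(lines) %% 4 != 0)
      stop("FASTQ-style tag file has a truncated record: ", path)
    lines <- lines[seq(2, length(lines), by = 4)]
  }
  toupper(lines[nzchar(lines)])
}

#' Write a raw tag library as one tag per line
#'
#' @param tags character vector of tag observations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tag_library <- function(tags, path) {
  writeLines(tags, path)
  invisible(path)
}
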