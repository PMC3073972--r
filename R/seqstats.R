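#' N50 of a set of sequence lengths
#'
#' N50 is the length at which, after ordering all sequences from longest to
#' shortest and accumulating their lengths, the running sum first exceeds
#' half the total length. "Exceeds" is strict: a cumulative sum landing
#' exactly on half continues to the next (shorter) length. The returned
#' value is always a member of the input multiset.
#'
#' @param lengths integer/numeric vector of sequence lengths (all >= 1).
#' @return a single length (nt).
#' @examples
#' n50(c(6, 5, 4, 3, 2)) # total 20; 6, then 6+5 = 11 > 10 -> 5
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50: empty length set")
  if (anyNA(lengths) || any(lengths < 1)) stop("n50: lengths must be >= 1")
  s <- sort(lengths, decreasing = TRUE)   # keeps the input type
  cs <- cumsum(as.numeric(s))             # double accumulator, no overflow
  s[[which(cs > sum(as.numeric(s)) / 2)[[1]]]]
}

#' Mean sequence length
#'
#' @param lengths integer/numeric vector of sequence lengths.
#' @return mean length (real; reports conventionally round half-up to nt).
#' @export
mean_length <- function(lengths) {
  if (length(lengths) == 0) stop("mean_length: empty length set")
  sum(as.numeric(lengths)) / length(lengths)
}

#' Length-class histogram
#'
#' Counts sequences per half-open interval `[b_i, b_{i+1})` over the supplied
#' class boundaries, with a final open-ended class `[b_k, Inf)`. A boundary
#' value (e.g. 200 with boundaries 100,200,300) falls in the upper class.
#'
#' @param lengths sequence lengths.
#' @param boundaries strictly increasing lower class bounds,
#'   e.g. `c(100, 200, 300, 400, 500)`.
#' @return data.frame with `class`, `count` and `percent` (2 dp, half-up).
#' @export
length_class_counts <- function(lengths, boundaries = c(100, 200, 300, 400, 500)) {
  stopifnot(length(boundaries) >= 1, !is.unsorted(boundaries, strictly = TRUE))
  lengths <- as.numeric(lengths)
  if (any(lengths < boundaries[[1]]))
    warning("lengths below the first class boundary counted in the first class")
  k <- length(boundaries)
  idx <- pmax(findInterval(lengths, boundaries), 1L)
  counts <- tabulate(idx, nbins = k)
  upper <- c(boundaries[-1], Inf)
  labs <- ifelse(is.finite(upper),
                 paste0(boundaries, "~", upper),
                 paste0(">=", boundaries))
  data.frame(class = labs, count = counts,
             percent = round_half_up(100 * counts / length(lengths), 2))
}

#' RPKM normalisation
#'
#' Reads per kilobase of feature per million mapped reads:
#' `1e9 * C / (N * L)` for `C` reads mapped to a feature of length `L` nt in
#' a library of `N` mapped reads.
#'
#' @param mapped_count reads mapped to the feature.
#' @param total_mapped total mapped reads in the library (>= 1).
#' @param feature_length feature length in nt (>= 1).
#' @return RPKM value(s), vectorised over the arguments.
#' @export
rpkm <- function(mapped_count, total_mapped, feature_length) {
  if (any(total_mapped < 1)) stop("rpkm: total_mapped must be >= 1")
  if (any(feature_length < 1)) stop("rpkm: feature_length must be >= 1")
  1e9 * mapped_count / (total_mapped * feature_length)
}

#' Assembly summary statistics
#'
#' Bundles sequence count, total and mean length, N50 and the length-class
#' distribution for a sequence set, as reported for de novo transcriptome
#' assemblies.
#'
#' @param lengths sequence lengths, or a named character vector of sequences
#'   (as from [read_unigene_fasta()]), in which case `nchar()` is taken.
#' @param boundaries class boundaries, see [length_class_counts()].
#' @return object of class `assembly_stats`: list with `n_sequences`,
#'   `total_length`, `mean_length` (real), `mean_length_report` (nt, half-up),
#'   `n50`, `classes`.
#' @export
assembly_stats <- function(lengths, boundaries = c(100, 200, 300, 400, 500)) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  out <- list(
    n_sequences = length(lengths),
    total_length = sum(as.numeric(lengths)),
    mean_length = mean_length(lengths),
    mean_length_report = round_half_up(mean_length(lengths)),
    n50 = n50(lengths),
    classes = length_class_counts(lengths, boundaries)
  )
  structure(out, class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly: %d sequences, %.0f nt total, mean %d nt, N50 %d nt\n",
              x$n_sequences, x$total_length, x$mean_length_report, x$n50))
  print(x$classes, row.names = FALSE)
  invisible(x)
}
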