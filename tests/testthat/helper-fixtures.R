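# shared fixture builders; everything is generated in code, no stored data

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_tag17 <- function(k) {
  out <- unique(vapply(seq_len(2 * k + 10), function(i) random_dna(17), character(1)))
  out[seq_len(k)]
}

# builds unigenes each carrying exactly one given tag17 at its 3'-most CATG
# site, plus the matching index and per-stage clean tag tables, so that
# mapping/screening tests can state expected outcomes directly from a
# tag x stage count matrix (0 = absent; nonzero counts must be >= 2)
profile_fixture <- function(counts, tags = NULL, stages = colnames(counts)) {
  k <- nrow(counts)
  if (is.null(tags)) tags <- random_tag17(k)
  # leading pad avoids accidental CATG after the planted site by construction:
  # the tag is the final 17 nt, so the planted site is always 3'-most
  unigenes <- vapply(seq_len(k), function(i)
    paste0(gsub("CATG", "AAAA", random_dna(40), fixed = TRUE),
           "CATG", tags[[i]]), character(1))
  names(unigenes) <- sprintf("G%03d", seq_len(k))
  index <- build_tag_index(unigenes, mode = "canonical")
  clean <- lapply(stages, function(s) {
    j <- match(s, stages)
    keep <- counts[, j] > 0
    data.frame(tag17 = tags[keep], count = as.integer(counts[keep, j]),
               stringsAsFactors = FALSE)
  })
  names(clean) <- stages
  list(unigenes = unigenes, tags = tags, index = index, clean = clean,
       profile = map_tags(clean, index))
}

# independent naive CATG site scanner (position-by-position substring test)
naive_tag_sites <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 21) return(integer(0))
  starts <- seq_len(n - 3)
  hits <- starts[substring(sequence, starts, starts + 3) == "CATG"]
  hits <- hits[hits + 20 <= n]
  if (!length(hits)) return(integer(0))
  hits[!grepl("N", substring(sequence, hits + 4, hits + 20), fixed = TRUE)]
}

# independent N50 oracle: literal walk of the definition
naive_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  acc <- 0
  for (L in s) {
    acc <- acc + L
    if (acc > half) return(L)
  }
}
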