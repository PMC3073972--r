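#' Clean-tag filtering with full accounting
#'
#' Applies the three raw-tag filters in a fixed order so that every removed
#' observation is attributed to exactly one category and the accounting is
#' additive in both units:
#' \enumerate{
#'   \item low quality: the observation contains at least one N;
#'   \item adaptor: the observation equals, or begins with, one of the
#'     supplied adaptor sequences;
#'   \item copy number: surviving observations are aggregated by tag
#'     identity and tags seen fewer than 2 times are dropped.
#' }
#' Identities enforced on the result, in total-tag and unique-tag units:
#' `raw = lowq + adaptor + singleton + clean`. Singletons have copy number
#' exactly 1, so `singleton_total == singleton_unique`.
#'
#' @param observations character vector of raw tag observations. With
#'   `dialect = "tag21"` (default) each must be 21 nt and, unless it
#'   contains an N, start with the CATG anchor; with `"tag17"` each must be
#'   a bare 17 nt tag.
#' @param adaptor_sequences character vector of adaptor sequences
#'   (default empty).
#' @param library_label label for the library (e.g. the stage).
#' @param dialect `"tag21"` or `"tag17"`.
#' @return list with
#'   \describe{
#'     \item{clean}{object of class `clean_tag_table`: data.frame
#'       `tag17`, `count` (all counts >= 2, no Ns), with attributes
#'       `library` and `clean_total`.}
#'     \item{accounting}{one-row data.frame of class `filter_accounting`
#'       (see [filter_accounting()]).}
#'   }
#' @export
filter_tags <- function(observations, adaptor_sequences = character(),
                        library_label = "library",
                        dialect = c("tag21", "tag17")) {
  dialect <- match.arg(dialect)
  observations <- toupper(observations)
  want <- if (dialect == "tag21") 21L else 17L
  bad <- which(nchar(observations) != want)
  if (length(bad))
    stop(sprintf("filter_tags: record %d has length %d, expected %d nt",
                 bad[[1]], nchar(observations[[bad[[1]]]]), want))
  is_lowq <- grepl("N", observations, fixed = TRUE)
  if (dialect == "tag21") {
    malformed <- which(!is_lowq & !startsWith(observations, "CATG"))
    if (length(malformed))
      stop(sprintf("filter_tags: record %d lacks the CATG anchor prefix",
                   malformed[[1]]))
  }
  is_adaptor <- rep(FALSE, length(observations))
  for (ad in toupper(adaptor_sequences))
    is_adaptor <- is_adaptor | observations == ad | startsWith(observations, ad)
  is_adaptor <- is_adaptor & !is_lowq

  rest <- observations[!is_lowq & !is_adaptor]
  tag17 <- if (dialect == "tag21") substring(rest, 5L, 21L) else rest
  tab <- table(tag17)
  counts <- as.integer(tab)
  singletons <- counts == 1L
  clean <- data.frame(tag17 = as.character(names(tab)[!singletons]),
                      count = counts[!singletons],
                      stringsAsFactors = FALSE)
  clean <- clean[order(clean$tag17), , drop = FALSE]
  rownames(clean) <- NULL

  acc <- filter_accounting(
    library = library_label,
    raw_total = length(observations),
    raw_unique = length(unique(observations)),
    lowq_total = sum(is_lowq),
    lowq_unique = length(unique(observations[is_lowq])),
    adaptor_total = sum(is_adaptor),
    adaptor_unique = length(unique(observations[is_adaptor])),
    singleton_total = sum(singletons),
    singleton_unique = sum(singletons)
  )
  structure_clean <- structure(clean, class = c("clean_tag_table", "data.frame"),
                               library = library_label,
                               clean_total = sum(clean$count))
  list(clean = structure_clean, accounting = acc)
}

#' Construct (and validate) a filter accounting record
#'
#' Builds the per-library accounting row of the clean-tag filter from its
#' components, deriving the clean counts from the additive identities
#' `clean = raw - lowq - adaptor - singleton` in both total-tag and
#' unique-tag units. Useful both as the output container of
#' [filter_tags()] and for checking published filter tables whose raw
#' observations are unavailable.
#'
#' @param library library label.
#' @param raw_total,raw_unique raw observation counts (total / distinct).
#' @param lowq_total,lowq_unique N-containing counts.
#' @param adaptor_total,adaptor_unique adaptor-matching counts.
#' @param singleton_total,singleton_unique copy-number-1 counts (must be
#'   equal).
#' @return one-row data.frame of class `filter_accounting` with the nine
#'   inputs plus derived `clean_total` and `clean_unique`.
#' @export
filter_accounting <- function(library, raw_total, raw_unique,
                              lowq_total, lowq_unique,
                              adaptor_total, adaptor_unique,
                              singleton_total, singleton_unique) {
  if (singleton_total != singleton_unique)
    stop("filter_accounting: singletons have copy number 1, so total and unique counts must agree")
  clean_total <- raw_total - lowq_total - adaptor_total - singleton_total
  clean_unique <- raw_unique - lowq_unique - adaptor_unique - singleton_unique
  if (clean_total < 0 || clean_unique < 0)
    stop("filter_accounting: removed counts exceed raw counts")
  structure(data.frame(
    library = library,
    raw_total = raw_total, raw_unique = raw_unique,
    lowq_total = lowq_total, lowq_unique = lowq_unique,
    adaptor_total = adaptor_total, adaptor_unique = adaptor_unique,
    singleton_total = singleton_total, singleton_unique = singleton_unique,
    clean_total = clean_total, clean_unique = clean_unique,
    stringsAsFactors = FALSE
  ), class = c("filter_accounting", "data.frame"))
}

#' Merge per-library accountings into a report table
#'
#' Lays the accounting rows out in the conventional report shape: one row
#' per filter category (raw, low quality, adaptors, copy number < 2,
#' clean), with a Total and a Unique column per library.
#'
#' @param accountings list of [filter_accounting()] rows (or a single
#'   data.frame with one row per library).
#' @return data.frame with a `category` column and `<library>_total`,
#'   `<library>_unique` column pairs.
#' @export
merge_accounting <- function(accountings) {
  if (is.data.frame(accountings)) accountings <- split(accountings, seq_len(nrow(accountings)))
  if (!length(accountings)) stop("merge_accounting: need at least one library")
  acc <- do.call(rbind, accountings)
  if (anyDuplicated(acc$library))
    stop("merge_accounting: duplicate library label: ",
         acc$library[duplicated(acc$library)][[1]])
  cats <- c(raw = "raw", lowq = "low_quality", adaptor = "adaptors",
            singleton = "copynum_lt2", clean = "clean")
  out <- data.frame(category = unname(cats), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(acc))) {
    lib <- acc$library[[i]]
    out[[paste0(lib, "_total")]]  <- as.numeric(acc[i, paste0(names(cats), "_total")])
    out[[paste0(lib, "_unique")]] <- as.numeric(acc[i, paste0(names(cats), "_unique")])
  }
  out
}

#' Expand a clean tag table back into observations
#'
#' Repeats each tag by its count; with `dialect = "tag21"` the CATG anchor
#' is restored. Mostly used to state idempotence: re-filtering the
#' expansion returns the same table.
#'
#' @param clean a `clean_tag_table`.
#' @param dialect output dialect, see [filter_tags()].
#' @return character vector of observations.
#' @export
expand_clean_tags <- function(clean, dialect = c("tag21", "tag17")) {
  dialect <- match.arg(dialect)
  tags <- rep(clean$tag17, clean$count)
  if (dialect == "tag21") paste0("CATG", tags) else tags
}
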