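#' Extract virtual DGE tags from one transcript
#'
#' Scans the sense strand for occurrences of the NlaIII recognition site
#' CATG and emits, for each site followed by at least 17 nt, the virtual
#' 21 nt tag (`CATG` + 17 nt downstream). Sites whose 17 nt extension
#' contains an ambiguous base (N) are skipped, as are sites with fewer than
#' 17 nt downstream. `rank_from_3prime` numbers the eligible sites from the
#' 3' end (1 = closest to the 3' terminus); the rank-1 site is the
#' canonical tag, the one an oligo-dT-anchored NlaIII DGE library is
#' expected to produce.
#'
#' @param sequence a DNA string over `A,C,G,T,N` (case-insensitive).
#' @param unigene_id identifier recorded on each returned tag.
#' @return data.frame with columns `unigene_id`, `tag17`, `full21`,
#'   `site_position` (0-based offset of the C of CATG), `rank_from_3prime`,
#'   `is_canonical`. Zero rows when no eligible site exists.
#' @export
extract_virtual_tags <- function(sequence, unigene_id = NA_character_) {
  sequence <- toupper(sequence)
  empty <- data.frame(unigene_id = character(), tag17 = character(),
                      full21 = character(), site_position = integer(),
                      rank_from_3prime = integer(), is_canonical = logical(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  if (grepl("[^ACGTN]", sequence))
    stop("extract_virtual_tags: sequence contains characters outside {A,C,G,T,N}")
  # CATG cannot overlap itself, so non-overlapping search finds every site
  hits <- gregexpr("CATG", sequence, fixed = TRUE)[[1]]
  if (hits[[1]] == -1L) return(empty)
  pos1 <- as.integer(hits)                       # 1-based position of C
  pos1 <- pos1[pos1 + 20L <= nchar(sequence)]    # need 17 nt after CATG
  if (!length(pos1)) return(empty)
  tag17 <- substring(sequence, pos1 + 4L, pos1 + 20L)
  keep <- !grepl("N", tag17, fixed = TRUE)
  pos1 <- pos1[keep]; tag17 <- tag17[keep]
  if (!length(pos1)) return(empty)
  rk <- rank(-pos1)                              # 3'-most site gets rank 1
  data.frame(unigene_id = unigene_id, tag17 = tag17,
             full21 = paste0("CATG", tag17),
             site_position = pos1 - 1L,
             rank_from_3prime = as.integer(rk),
             is_canonical = rk == 1L,
             stringsAsFactors = FALSE)
}

#' Canonical virtual tag of a transcript
#'
#' The eligible CATG site closest to the 3' end (maximal position).
#'
#' @inheritParams extract_virtual_tags
#' @return one-row data.frame as in [extract_virtual_tags()], or `NULL`
#'   when the sequence has no eligible site.
#' @export
canonical_tag <- function(sequence, unigene_id = NA_character_) {
  tags <- extract_virtual_tags(sequence, unigene_id)
  if (!nrow(tags)) return(NULL)
  tags[tags$is_canonical, , drop = FALSE]
}

#' Build the virtual tag index for a unigene set
#'
#' Extracts virtual tags from every unigene and indexes them by their 17 nt
#' identity (the CATG anchor is constant and carries no information). A
#' tag17 observed in two or more distinct unigenes is classed `ambiguous`;
#' mapped observations of such tags cannot be attributed to a single
#' transcript and are excluded from expression counts downstream.
#'
#' @param unigenes named character vector of DNA sequences; names are the
#'   unigene identifiers and must be unique.
#' @param mode `"canonical"` indexes only each unigene's 3'-most tag
#'   (matches NlaIII DGE chemistry); `"all"` indexes every eligible site.
#' @return object of class `virtual_tag_index`: list with
#'   \describe{
#'     \item{sites}{data.frame of every indexed site (see
#'       [extract_virtual_tags()]).}
#'     \item{tag_class}{named character vector, tag17 -> `"unique"` or
#'       `"ambiguous"`.}
#'     \item{tag_unigene}{named character vector mapping each *unique*
#'       tag17 to its unigene id.}
#'     \item{unigenes_without_sites}{ids with no eligible site.}
#'     \item{mode}{the indexing mode.}
#'   }
#' @export
build_tag_index <- function(unigenes, mode = c("canonical", "all")) {
  mode <- match.arg(mode)
  ids <- names(unigenes)
  if (is.null(ids) || anyNA(ids) || !all(nzchar(ids)))
    stop("build_tag_index: unigenes must be a named vector")
  if (anyDuplicated(ids))
    stop("build_tag_index: duplicate unigene id: ",
         ids[duplicated(ids)][[1]])
  per <- lapply(seq_along(unigenes), function(i)
    extract_virtual_tags(unigenes[[i]], ids[[i]]))
  sites <- do.call(rbind, per)
  if (is.null(sites) || !nrow(sites)) {
    sites <- extract_virtual_tags("", "x")[0, ]
  } else if (mode == "canonical") {
    sites <- sites[sites$is_canonical, , drop = FALSE]
  }
  # ambiguity is about distinct unigenes, not repeated sites within one
  n_uni <- tapply(sites$unigene_id, sites$tag17,
                  function(u) length(unique(u)))
  tag_class <- ifelse(n_uni > 1L, "ambiguous", "unique")
  uniq <- names(tag_class)[tag_class == "unique"]
  tag_unigene <- sites$unigene_id[match(uniq, sites$tag17)]
  names(tag_unigene) <- uniq
  structure(list(
    sites = sites,
    tag_class = tag_class,
    tag_unigene = tag_unigene,
    unigenes_without_sites = setdiff(ids, unique(sites$unigene_id)),
    mode = mode
  ), class = "virtual_tag_index")
}

#' @export
print.virtual_tag_index <- function(x, ...) {
  cat(sprintf(
    "Virtual tag index (%s mode): %d sites, %d distinct tag17 (%d unique, %d ambiguous), %d unigenes without sites\n",
    x$mode, nrow(x$sites), length(x$tag_class),
    sum(x$tag_class == "unique"), sum(x$tag_class == "ambiguous"),
    length(x$unigenes_without_sites)))
  invisible(x)
}

#' Write a virtual tag index as TSV
#'
#' One row per indexed site: tag17, unigene id, 1-based site position,
#' rank from the 3' end, canonical flag, uniqueness class.
#'
#' @param index a [build_tag_index()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tag_index <- function(index, path) {
  df <- index$sites
  out <- data.frame(tag17 = df$tag17, unigene_id = df$unigene_id,
                    position_1based = df$site_position + 1L,
                    rank_from_3prime = df$rank_from_3prime,
                    canonical = df$is_canonical,
                    uniqueness = unname(index$tag_class[df$tag17]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
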