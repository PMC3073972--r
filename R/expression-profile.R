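#' Map clean tag tables onto the virtual tag index
#'
#' Exact tag17 lookup of each stage's clean tags against the index. Tags
#' hitting a unique index entry credit their unigene; tags hitting an
#' ambiguous entry are tallied separately and never credit any unigene;
#' tags absent from the index are tallied unmapped. The conservation
#' identity `mapped_unique + ambiguous + unmapped = clean_total` is
#' asserted for every stage.
#'
#' @param clean_tables named list of `clean_tag_table`s, one per stage;
#'   names are the stage labels in report order.
#' @param index a [build_tag_index()] result.
#' @return object of class `stage_profile`: list with
#'   \describe{
#'     \item{stages}{stage labels.}
#'     \item{tag_counts}{data.frame `tag17`, `status`
#'       (unique/ambiguous/unmapped), `unigene_id` (NA unless unique), one
#'       count column per stage.}
#'     \item{unigene_counts}{data.frame `unigene_id` + one count column per
#'       stage (sums of uniquely mapping tags only).}
#'     \item{clean_total, mapped_unique, ambiguous, unmapped}{named
#'       per-stage totals (in tag observations).}
#'   }
#' @export
map_tags <- function(clean_tables, index) {
  stages <- names(clean_tables)
  if (is.null(stages) || anyDuplicated(stages))
    stop("map_tags: clean_tables must be a uniquely named list of stages")
  if (!length(index$tag_class)) stop("map_tags: empty tag index")

  all_tags <- sort(unique(unlist(lapply(clean_tables, `[[`, "tag17"))))
  cls <- unname(index$tag_class[all_tags])
  status <- ifelse(is.na(cls), "unmapped", cls)
  unigene <- ifelse(status == "unique",
                    unname(index$tag_unigene[all_tags]), NA_character_)

  tag_counts <- data.frame(tag17 = all_tags, status = status,
                           unigene_id = unigene, stringsAsFactors = FALSE)
  for (s in stages) {
    ct <- clean_tables[[s]]
    v <- ct$count[match(all_tags, ct$tag17)]
    tag_counts[[s]] <- ifelse(is.na(v), 0L, v)
  }

  clean_total <- vapply(clean_tables, function(ct) sum(ct$count), numeric(1))
  sums_by <- function(st) vapply(
    stages, function(s) sum(tag_counts[[s]][tag_counts$status == st]),
    numeric(1))
  mapped_unique <- sums_by("unique")
  ambiguous <- sums_by("ambiguous")
  unmapped <- sums_by("unmapped")
  stopifnot(all(mapped_unique + ambiguous + unmapped == clean_total))

  uq <- tag_counts[tag_counts$status == "unique", , drop = FALSE]
  ug_ids <- sort(unique(uq$unigene_id))
  unigene_counts <- data.frame(unigene_id = ug_ids, stringsAsFactors = FALSE)
  for (s in stages) {
    agg <- tapply(uq[[s]], uq$unigene_id, sum)
    unigene_counts[[s]] <- as.integer(agg[ug_ids])
  }

  structure(list(stages = stages, tag_counts = tag_counts,
                 unigene_counts = unigene_counts,
                 clean_total = clean_total, mapped_unique = mapped_unique,
                 ambiguous = ambiguous, unmapped = unmapped),
            class = "stage_profile")
}

#' @export
print.stage_profile <- function(x, ...) {
  cat(sprintf("Stage expression profile over %d stages (%s)\n",
              length(x$stages), paste(x$stages, collapse = ", ")))
  m <- rbind(clean_total = x$clean_total, mapped_unique = x$mapped_unique,
             ambiguous = x$ambiguous, unmapped = x$unmapped)
  print(m)
  cat(sprintf("%d distinct clean tags, %d unigenes with unique-tag counts\n",
              nrow(x$tag_counts), nrow(x$unigene_counts)))
  invisible(x)
}

#' Default copy-number bins
#'
#' Lower bounds of the standard clean-tag copy-number report bins:
#' 2, 3-9, 10-49, 50-99, 100-199, 200-299, 300-399, 400-499, 500-999,
#' 1000-1999, 2000-4999, 5000-9999, >= 10000.
#'
#' @return integer vector of bin lower bounds.
#' @export
default_copy_number_bins <- function() {
  c(2L, 3L, 10L, 50L, 100L, 200L, 300L, 400L, 500L,
    1000L, 2000L, 5000L, 10000L)
}

#' Copy-number distribution of clean tags
#'
#' Counts each stage's distinct clean tags into copy-number bins. Bins are
#' given as strictly increasing lower bounds starting at 2 (clean tags have
#' copy number >= 2 by construction), covering `[2, Inf)` without gaps or
#' overlap; the last bin is open-ended. Column totals equal each stage's
#' distinct clean tag count (`clean_unique`).
#'
#' @param clean_tables named list of `clean_tag_table`s.
#' @param bins bin lower bounds, see [default_copy_number_bins()].
#' @return data.frame `bin` label column, one column per stage, a `Total`
#'   column, and a final `Total` row.
#' @export
copy_number_distribution <- function(clean_tables,
                                     bins = default_copy_number_bins()) {
  if (is.unsorted(bins, strictly = TRUE) || bins[[1]] != 2)
    stop("copy_number_distribution: bins must be strictly increasing lower bounds starting at 2")
  upper <- c(bins[-1] - 1, Inf)
  labs <- ifelse(is.finite(upper),
                 ifelse(upper == bins, as.character(bins),
                        paste0(bins, "~", upper)),
                 paste0(">=", bins))
  out <- data.frame(bin = labs, stringsAsFactors = FALSE)
  for (s in names(clean_tables)) {
    ct <- clean_tables[[s]]
    if (any(ct$count < 2))
      stop("copy_number_distribution: clean table contains copy number < 2")
    out[[s]] <- tabulate(findInterval(ct$count, bins), nbins = length(bins))
    stopifnot(sum(out[[s]]) == nrow(ct))
  }
  stage_cols <- names(clean_tables)
  out$Total <- as.integer(rowSums(out[, stage_cols, drop = FALSE]))
  total_row <- c(list(bin = "Total"),
                 lapply(out[c(stage_cols, "Total")], sum))
  rbind(out, as.data.frame(total_row, stringsAsFactors = FALSE))
}

#' Venn partition of detected items across stages
#'
#' Assigns every detected item (tag or unigene with count > 0 in at least
#' one stage) to exactly one of the `2^k - 1` presence categories over the
#' k stages. Category counts are disjoint and sum to the union size.
#'
#' @param profile a [map_tags()] result.
#' @param level `"tag"` (all clean tags, whatever their mapping status) or
#'   `"unigene"` (uniquely mapped unigene counts).
#' @return data.frame `category` (stage names joined by `&`), `count`,
#'   covering all non-empty presence patterns (zeros included).
#' @export
venn_partition <- function(profile, level = c("tag", "unigene")) {
  level <- match.arg(level)
  stages <- profile$stages
  df <- if (level == "tag") profile$tag_counts else profile$unigene_counts
  m <- as.matrix(df[, stages, drop = FALSE]) > 0
  k <- length(stages)
  code <- as.vector(m %*% 2^(seq_len(k) - 1))
  if (!any(code > 0)) warning("venn_partition: no detected items")
  codes <- seq_len(2^k - 1)
  labs <- vapply(codes, function(cd)
    paste(stages[bitwAnd(cd, 2^(seq_len(k) - 1)) > 0], collapse = "&"),
    character(1))
  counts <- vapply(codes, function(cd) sum(code == cd), integer(1))
  data.frame(category = labs, count = counts, stringsAsFactors = FALSE)
}

#' Call stage-specific tags
#'
#' Identifies candidate RNAi target tags whose expression is confined to
#' (strict mode) or strongly dominated by (dominance mode) a single stage.
#' Only unambiguous, uniquely mapping tags are eligible. In strict mode a
#' tag is called for stage s when its count is nonzero in s only and at
#' least `min_count`. In dominance mode the called stage is the argmax
#' stage; the call stands when the fold dominance (called-stage count over
#' the maximal other-stage count, `Inf` when all others are zero) reaches
#' `fold_threshold` and the called-stage count reaches `min_count`. Within
#' each called stage, calls are ranked by descending count with
#' lexicographic tag17 tie-break.
#'
#' @param profile a [map_tags()] result.
#' @param mode `"dominance"` (default, fold >= 3, count >= 100) or
#'   `"strict"`.
#' @param min_count minimal called-stage count.
#' @param fold_threshold dominance threshold (> 1), ignored in strict mode.
#' @return data.frame of class `target_calls`: `unigene_id`, `tag17`, one
#'   count column per stage, `called_stage`, `fold_dominance`, `mode`,
#'   `rank` (within called stage).
#' @export
stage_specific_calls <- function(profile, mode = c("dominance", "strict"),
                                 min_count = 100, fold_threshold = 3) {
  mode <- match.arg(mode)
  if (min_count < 1) stop("stage_specific_calls: min_count must be >= 1")
  if (mode == "dominance" && fold_threshold <= 1)
    stop("stage_specific_calls: fold_threshold must exceed 1")
  stages <- profile$stages
  df <- profile$tag_counts[profile$tag_counts$status == "unique", , drop = FALSE]
  cnt <- as.matrix(df[, stages, drop = FALSE])
  top <- apply(cnt, 1, max)
  arg <- apply(cnt, 1, which.max)
  other <- vapply(seq_len(nrow(cnt)),
                  function(i) max(cnt[i, -arg[[i]]]), numeric(1))
  fold <- ifelse(other == 0, Inf, top / other)
  called <- if (mode == "strict") {
    top >= min_count & other == 0 & top > 0
  } else {
    # a tied argmax has fold 1 and is never called
    top >= min_count & fold >= fold_threshold
  }
  out <- data.frame(unigene_id = df$unigene_id[called],
                    tag17 = df$tag17[called], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cnt[called, , drop = FALSE]))
  out$called_stage <- stages[arg[called]]
  out$fold_dominance <- fold[called]
  out$mode <- mode
  rownames(out) <- NULL
  out$rank <- NA_integer_
  for (s in unique(out$called_stage)) {
    i <- which(out$called_stage == s)
    o <- order(-out[[s]][i], out$tag17[i])
    out$rank[i[o]] <- seq_along(i)
  }
  structure(out, class = c("target_calls", "data.frame"))
}

#' Rank called targets within a stage
#'
#' @param calls a [stage_specific_calls()] result.
#' @param stage stage to rank.
#' @param top_k optional truncation.
#' @return the stage's calls ordered by descending called-stage count
#'   (ties: lexicographic tag17).
#' @export
rank_targets <- function(calls, stage, top_k = Inf) {
  sub <- calls[calls$called_stage == stage, , drop = FALSE]
  if (!nrow(sub)) stop("rank_targets: no calls for stage ", stage)
  sub <- sub[order(sub$rank), , drop = FALSE]
  rownames(sub) <- NULL
  utils::head(sub, top_k)
}

#' Tags-per-million normalisation
#'
#' Scales a clean tag table's counts to a library size of one million:
#' `count * 1e6 / clean_total`. The normalised column sums to 1e6.
#'
#' @param clean a `clean_tag_table`.
#' @return the table with an added `tpm` column.
#' @export
tags_per_million <- function(clean) {
  total <- sum(clean$count)
  if (!nrow(clean) || total == 0) stop("tags_per_million: empty clean tag table")
  clean$tpm <- clean$count * 1e6 / total
  clean
}
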