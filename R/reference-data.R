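#' Published reference tables from the Asian corn borer DGE screen
#'
#' Small plain-text copies of the published summary tables of the
#' four-stage (egg/larva/pupa/adult) *Ostrinia furnacalis* DGE-tag RNAi
#' screening study, shipped under `inst/extdata/`. The raw reads behind
#' them were never deposited, so these printed summaries are the only
#' available reference inputs; the package uses them to cross-check its
#' accounting, binning and correction arithmetic.
#'
#' \describe{
#'   \item{`acb_filter_counts()`}{per-stage raw/low-quality/adaptor/
#'     copy-number-1/clean tag counts in total and unique units.}
#'   \item{`acb_copy_number()`}{distinct clean tags per copy-number bin
#'     and stage.}
#'   \item{`acb_target_tags()`}{the ten selected larval target tags with
#'     their per-stage copy numbers.}
#'   \item{`acb_bioassay()`}{egg hatch ratios and 1/3/5-day larval
#'     mortalities (mean ± sd) after spraying 50 ng/µl dsRNA, with the
#'     published 5-day control-corrected columns.}
#'   \item{`acb_assembly()`}{contig/scaffold/unigene assembly margins:
#'     length-class counts, N50, mean, count and total length.}
#' }
#'
#' @return a data.frame (see above).
#' @name acb_reference
NULL

acb_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dgescreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname acb_reference
#' @export
acb_filter_counts <- function() acb_extdata("acb_tag_filter_counts.tsv")

#' @rdname acb_reference
#' @export
acb_copy_number <- function() acb_extdata("acb_copy_number_distribution.tsv")

#' @rdname acb_reference
#' @export
acb_target_tags <- function() acb_extdata("acb_larval_target_tags.tsv")

#' @rdname acb_reference
#' @export
acb_bioassay <- function() acb_extdata("acb_bioassay_mortality.tsv")

#' @rdname acb_reference
#' @export
acb_assembly <- function() acb_extdata("acb_assembly_summary.tsv")
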