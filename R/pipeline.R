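#' Run the full synthetic screening pipeline
#'
#' End-to-end composition: simulate a study (unigenes, stage tag
#' libraries, bioassay, qPCR), build the virtual tag index, filter each
#' library to clean tags, map and profile expression across stages, call
#' and rank stage-specific RNAi targets, fit the dose-response, and
#' compute knockdown fold changes. All intermediate artefacts are written
#' as plain files (FASTA/TSV/JSON) under `out_dir` so any stage can be
#' re-run or inspected in isolation, and a JSON manifest records the
#' configuration hash and per-stage row counts. Outputs are byte-stable
#' for identical config + seed.
#'
#' @param config a [sim_config()]; its seed drives every draw.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file writing.
#' @param index_mode virtual-tag indexing mode, see [build_tag_index()].
#' @param screen_mode,min_count,fold_threshold screening parameters, see
#'   [stage_specific_calls()].
#' @param target_stage stage whose targets are ranked (default the second
#'   stage label, the larval position in the default layout).
#' @param top_k number of ranked targets to keep.
#' @param bioassay_lc50,bioassay_slope,bioassay_control,bioassay_doses,bioassay_n
#'   dose-response simulation parameters, see [simulate_bioassay()].
#' @param qpcr_folds named fold changes for the knockdown simulation.
#' @param sampling tag-library sampling mode, see [sample_tag_library()].
#' @return list of class `dge_pipeline_run` with elements `unigenes`,
#'   `truth`, `index`, `accounting`, `clean`, `profile`, `copy_number`,
#'   `venn_tag`, `venn_unigene`, `calls`, `targets`, `bioassay`, `fit`,
#'   `knockdown`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         index_mode = "canonical",
                         screen_mode = "dominance", min_count = 100,
                         fold_threshold = 3,
                         target_stage = config$stages[[min(2, length(config$stages))]],
                         top_k = 10,
                         bioassay_lc50 = 60, bioassay_slope = 4,
                         bioassay_control = 0.11,
                         bioassay_doses = c(20, 40, 60, 80, 100),
                         bioassay_n = 300,
                         qpcr_folds = c(day1 = 1.5, day3 = 0.6, day5 = 0.2),
                         sampling = "multinomial") {
  stopifnot(inherits(config, "sim_config"))
  emit <- function(df, file) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  unigenes <- generate_unigenes(config)
  if (!is.null(out_dir))
    write_unigene_fasta(unigenes, file.path(out_dir, "unigenes.fasta"))
  stats <- assembly_stats(unigenes)

  truth <- generate_expression_matrix(config, unigenes)
  index <- build_tag_index(unigenes, mode = index_mode)
  if (!is.null(out_dir)) write_tag_index(index, file.path(out_dir, "tag_index.tsv"))

  clean <- list(); accountings <- list()
  for (s in config$stages) {
    obs <- sample_tag_library(truth, s, config, sampling = sampling)
    if (!is.null(out_dir))
      write_tag_library(obs, file.path(out_dir, paste0("tags_", s, ".txt")))
    res <- filter_tags(obs, library_label = s)
    clean[[s]] <- res$clean
    accountings[[s]] <- res$accounting
    emit(res$clean, paste0("clean_", s, ".tsv"))
  }
  accounting <- merge_accounting(accountings)
  emit(accounting, "filter_accounting.tsv")

  profile <- map_tags(clean, index)
  emit(profile$unigene_counts, "unigene_counts.tsv")
  cn <- copy_number_distribution(clean)
  emit(cn, "copy_number_distribution.tsv")
  venn_tag <- venn_partition(profile, "tag")
  venn_unigene <- venn_partition(profile, "unigene")
  emit(venn_tag, "venn_tags.tsv")
  emit(venn_unigene, "venn_unigenes.tsv")

  calls <- stage_specific_calls(profile, mode = screen_mode,
                                min_count = min_count,
                                fold_threshold = fold_threshold)
  emit(as.data.frame(calls), "stage_specific_calls.tsv")
  targets <- if (any(calls$called_stage == target_stage))
    rank_targets(calls, target_stage, top_k) else calls[0, ]
  emit(as.data.frame(targets), "ranked_targets.tsv")

  assay <- simulate_bioassay(bioassay_lc50, bioassay_slope, bioassay_control,
                             bioassay_doses, bioassay_n,
                             seed = sub_seed(config$seed, 20))
  emit(assay, "bioassay.tsv")
  fit <- probit_fit(assay$dose, assay$n, assay$dead)
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(fit), file.path(out_dir, "lc50_fit.json"),
                         auto_unbox = TRUE, digits = NA)

  ct <- simulate_qpcr(qpcr_folds, gene = "target", calibrator = "untreated",
                      noise_sd = 0.2, seed = sub_seed(config$seed, 21))
  emit(ct, "qpcr_ct.tsv")
  knock <- knockdown_profile(ct, "untreated")
  emit(knock, "knockdown.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("dgescreen")),
    config = unclass(config),
    stages = config$stages,
    rows = list(unigenes = length(unigenes),
                indexed_sites = nrow(index$sites),
                clean_unique = vapply(clean, nrow, integer(1)),
                calls = nrow(calls)))
  if (!is.null(out_dir)) {
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(unigenes = unigenes, stats = stats, truth = truth,
                 index = index, accounting = accounting, clean = clean,
                 profile = profile, copy_number = cn, venn_tag = venn_tag,
                 venn_unigene = venn_unigene, calls = calls,
                 targets = targets, bioassay = assay, fit = fit,
                 knockdown = knock, manifest = manifest),
            class = "dge_pipeline_run")
}

#' @export
print.dge_pipeline_run <- function(x, ...) {
  cat("DGE screening pipeline run\n")
  print(x$index)
  print(x$profile)
  cat(sprintf("%d stage-specific calls (%s mode); LC50 estimate %.2f\n",
              nrow(x$calls), x$calls$mode[1] %||% "-", x$fit$lc50))
  invisible(x)
}
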