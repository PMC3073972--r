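#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' Livak relative quantification with a fixed amplification efficiency of
#' 2. Per replicate, `dCt = ct_target - ct_reference`; per sample, dCt
#' replicates are averaged on the Ct scale; `ddCt` is the sample mean dCt
#' minus the calibrator mean dCt and the fold change is `2^-ddCt`.
#' Replicate scatter is propagated as the range `2^-(ddCt +/- sd)` where
#' sd is the sample's dCt standard deviation.
#'
#' @param records data.frame with columns `sample`, `gene`, `ct_target`,
#'   `ct_reference`, `replicate`.
#' @param calibrator sample label used as the calibrator (fold 1).
#' @return data.frame `gene`, `sample`, `n_replicates`, `delta_ct`,
#'   `delta_ct_sd`, `ddct`, `fold`, `fold_lo`, `fold_hi`.
#' @export
relative_expression <- function(records, calibrator) {
  need <- c("sample", "gene", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("relative_expression: records need columns ", paste(need, collapse = ", "))
  if (anyNA(records$ct_reference) || anyNA(records$ct_target))
    stop("relative_expression: missing Ct value (reference-gene record absent for some sample)")
  if (any(records$ct_target <= 0 | records$ct_reference <= 0) ||
      any(!is.finite(records$ct_target) | !is.finite(records$ct_reference)))
    stop("relative_expression: Ct values must be positive and finite")
  if (!calibrator %in% records$sample)
    stop("relative_expression: calibrator sample '", calibrator, "' not present")
  records$dct <- records$ct_target - records$ct_reference
  out <- do.call(rbind, lapply(split(records, records[c("sample", "gene")], drop = TRUE),
    function(d) data.frame(gene = d$gene[[1]], sample = d$sample[[1]],
                           n_replicates = nrow(d),
                           delta_ct = mean(d$dct),
                           delta_ct_sd = if (nrow(d) > 1) stats::sd(d$dct) else 0,
                           stringsAsFactors = FALSE)))
  res <- do.call(rbind, lapply(split(out, out$gene), function(g) {
    cal <- g$delta_ct[g$sample == calibrator]
    if (!length(cal))
      stop("relative_expression: calibrator has no records for gene ", g$gene[[1]])
    g$ddct <- g$delta_ct - cal
    g$fold <- 2^(-g$ddct)
    g$fold_lo <- 2^(-(g$ddct + g$delta_ct_sd))
    g$fold_hi <- 2^(-(g$ddct - g$delta_ct_sd))
    g
  }))
  rownames(res) <- NULL
  res
}

#' Post-treatment knockdown profile
#'
#' Relative expression of each gene at each sampled day versus the
#' untreated calibrator, with an up/down direction flag. Sample labels
#' other than the calibrator are interpreted as time points (e.g.
#' `day1`, `day3`, `day5`).
#'
#' @inheritParams relative_expression
#' @return the [relative_expression()] table restricted to non-calibrator
#'   samples, with an added `direction` column (`"up"`, `"down"`,
#'   `"unchanged"` vs fold 1).
#' @export
knockdown_profile <- function(records, calibrator) {
  res <- relative_expression(records, calibrator)
  res <- res[res$sample != calibrator, , drop = FALSE]
  res$direction <- ifelse(res$fold > 1, "up",
                          ifelse(res$fold < 1, "down", "unchanged"))
  rownames(res) <- NULL
  res
}
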