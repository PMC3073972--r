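#' Replicate mortality summary
#'
#' Per-replicate percent mortality with unweighted mean and sample
#' standard deviation (n - 1), as printed in bioassay report tables.
#'
#' @param dead dead counts per replicate.
#' @param n number of insects per replicate (all > 0).
#' @return list with `mean`, `sd` (both 2 dp, half-up), `n_replicates`,
#'   and `sd_defined` (FALSE for a single replicate, where sd is reported
#'   as 0).
#' @export
mortality_percent <- function(dead, n) {
  if (!length(dead)) stop("mortality_percent: need at least one replicate")
  if (length(n) == 1) n <- rep(n, length(dead))
  if (any(n <= 0)) stop("mortality_percent: n_insects must be positive")
  if (any(dead < 0 | dead > n)) stop("mortality_percent: dead must lie in [0, n]")
  pct <- 100 * dead / n
  sd_def <- length(pct) > 1
  list(mean = round_half_up(mean(pct), 2),
       sd = if (sd_def) round_half_up(stats::sd(pct), 2) else 0,
       n_replicates = length(pct), sd_defined = sd_def)
}

#' Abbott control-corrected mortality
#'
#' `(T - C) / (100 - C) * 100` for treatment mortality T % and control
#' mortality C %. Treatments with raw mortality below the control produce a
#' negative value, which is clamped to 0 and flagged via the `clamped`
#' attribute.
#'
#' @param raw_pct treatment mortality, percent.
#' @param control_pct control mortality, percent (< 100).
#' @param digits decimal places for the reported value (default 2,
#'   half-up); use `NULL` for no rounding.
#' @return corrected mortality percent, vectorised; attribute `clamped`
#'   marks entries clamped at 0.
#' @export
abbott_corrected <- function(raw_pct, control_pct, digits = 2) {
  if (any(raw_pct < 0 | raw_pct > 100) || any(control_pct < 0 | control_pct > 100))
    stop("abbott_corrected: percentages must lie in [0, 100]")
  if (any(control_pct == 100)) stop("abbott_corrected: control mortality of 100% leaves nothing to correct")
  out <- (raw_pct - control_pct) / (100 - control_pct) * 100
  clamped <- out < 0
  out[clamped] <- 0
  if (!is.null(digits)) out <- round_half_up(out, digits)
  attr(out, "clamped") <- clamped
  out
}

#' Probit dose-response fit with LC50 and fiducial limits
#'
#' Maximum-likelihood probit regression of mortality on log10 dose
#' (iteratively reweighted least squares via [stats::glm()]), with
#' `LC50 = 10^(-intercept/slope)`. Control mortality, when a dose-0 row is
#' present and `control_handling = "abbott"`, is removed by Abbott
#' pre-correction of the observed proportions before fitting. 95% fiducial
#' limits for the LC50 follow Fieller's theorem on the log10 scale; when
#' the Pearson heterogeneity factor (chi-square / df) exceeds 1 the
#' variance matrix is inflated by it and the normal multiplier is replaced
#' by Student's t on the residual df. When Fieller's g >= 1 the interval
#' is degenerate and a delta-method interval is returned with
#' `interval_method = "delta"`.
#'
#' @param doses dose per group; include a 0 row for the control.
#' @param n subjects per group.
#' @param dead dead subjects per group.
#' @param control_handling `"abbott"` (default) or `"none"`.
#' @param link `"probit"` (default) or `"logit"` (reported intercept/slope
#'   are then on the logit scale; the LC50 inversion is unchanged).
#' @param conf_level fiducial confidence level, default 0.95.
#' @return object of class `dose_response_fit`: list with `slope`,
#'   `intercept` (per log10 dose), `lc50`, `ci95` (dose units),
#'   `interval_method` ("fieller" or "delta"), `g`, `heterogeneity`,
#'   `deviance`, `df`, `converged`, `control_mortality` (proportion used
#'   for correction, NA if none), `n_doses`.
#' @export
probit_fit <- function(doses, n, dead,
                       control_handling = c("abbott", "none"),
                       link = c("probit", "logit"), conf_level = 0.95) {
  control_handling <- match.arg(control_handling)
  link <- match.arg(link)
  stopifnot(length(doses) == length(n), length(doses) == length(dead))
  if (any(doses < 0)) stop("probit_fit: negative dose")
  ctrl <- doses == 0
  c_obs <- NA_real_
  if (any(ctrl)) {
    c_obs <- sum(dead[ctrl]) / sum(n[ctrl])
    doses <- doses[!ctrl]; dead <- dead[!ctrl]; n <- n[!ctrl]
  }
  if (length(unique(doses)) < 2)
    stop("probit_fit: need at least two distinct positive doses")
  p <- dead / n
  if (control_handling == "abbott" && !is.na(c_obs) && c_obs > 0) {
    if (c_obs >= 1) stop("probit_fit: control mortality is 100%")
    p <- pmax((p - c_obs) / (1 - c_obs), 0)
  }
  if (all(p == 0) || all(p == 1))
    stop("probit_fit: no dose-response information (all 0% or all 100% after correction)")
  x <- log10(doses)
  fit <- suppressWarnings(
    stats::glm(p ~ x, family = stats::binomial(link = link), weights = n))
  a <- unname(stats::coef(fit)[[1]]); b <- unname(stats::coef(fit)[[2]])
  if (!is.finite(b) || b <= 0)
    stop("probit_fit: non-positive slope; the response is not monotone increasing in dose")
  if (diff(range(p)) == 0)
    stop("probit_fit: degenerate response (identical mortality at every dose)")

  mu <- stats::fitted(fit)
  pearson <- sum(n * (p - mu)^2 / (mu * (1 - mu)))
  df <- length(doses) - 2L
  het <- if (df > 0) pearson / df else NA_real_
  V <- stats::summary.glm(fit)$cov.unscaled
  alpha <- 1 - conf_level
  if (!is.na(het) && het > 1) {
    V <- V * het
    tcrit <- stats::qt(1 - alpha / 2, df)
  } else {
    tcrit <- stats::qnorm(1 - alpha / 2)
  }
  vaa <- V[1, 1]; vab <- V[1, 2]; vbb <- V[2, 2]
  m <- -a / b                               # log10 LC50
  g <- tcrit^2 * vbb / b^2
  if (is.finite(g) && g < 1) {
    disc <- vaa + 2 * m * vab + m^2 * vbb - g * (vaa - vab^2 / vbb)
    half <- tcrit / (b * (1 - g)) * sqrt(disc)
    centre <- m + g / (1 - g) * (m + vab / vbb)
    ci <- 10^c(centre - half, centre + half)
    method <- "fieller"
  } else {
    # slope too uncertain for Fieller: first-order delta interval
    vm <- (vaa + 2 * m * vab + m^2 * vbb) / b^2
    ci <- 10^(m + c(-1, 1) * tcrit * sqrt(vm))
    method <- "delta"
  }
  structure(list(slope = b, intercept = a, link = link,
                 lc50 = 10^m, ci95 = ci, conf_level = conf_level,
                 interval_method = method, g = g, heterogeneity = het,
                 deviance = stats::deviance(fit), df = df,
                 converged = fit$converged, control_mortality = c_obs,
                 n_doses = length(doses)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s dose-response fit on log10(dose): slope %.3f, intercept %.3f\n",
              x$link, x$slope, x$intercept))
  cat(sprintf("LC50 = %.4g (%.0f%% %s limits %.4g - %.4g)\n",
              x$lc50, 100 * x$conf_level, x$interval_method,
              x$ci95[[1]], x$ci95[[2]]))
  cat(sprintf("deviance %.3f on %d df; heterogeneity %.3f; g = %.3f\n",
              x$deviance, x$df, x$heterogeneity, x$g))
  invisible(x)
}

#' Egg hatch ratio summary
#'
#' Per-replicate hatch percentage with mean and sample sd, as in
#' [mortality_percent()].
#'
#' @param hatched hatched counts per replicate.
#' @param total eggs per replicate (all >= 1).
#' @return list with `mean`, `sd`, `n_replicates`, `sd_defined`.
#' @export
hatch_ratio <- function(hatched, total) {
  if (any(total < 1)) stop("hatch_ratio: egg totals must be >= 1")
  mortality_percent(hatched, total)
}
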