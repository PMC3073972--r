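#' Simulation configuration for the synthetic DGE study
#'
#' Parameters describing the simulated study: a de novo unigene set, four
#' developmental-stage tag libraries with sequencing noise, and the
#' expression structure (stage-specific vs shared transcripts) behind
#' them. Defaults mirror the scale and structure of a four-stage insect
#' DGE screen: four libraries of 3.5 million 21 nt tags each over a
#' transcriptome in which a substantial minority of transcripts is
#' expressed in exactly one stage.
#'
#' @param n_unigenes number of simulated unigenes.
#' @param length_range c(min, max) unigene length in nt, sampled
#'   uniformly; min >= 21 so a guaranteed tag site always fits.
#' @param gc_fraction GC content of simulated sequence.
#' @param stages stage labels, in report order.
#' @param specific_fraction_per_stage probability a unigene is expressed in
#'   exactly one given stage; scalar (recycled) or one value per stage;
#'   the sum must be <= 1, the remainder being shared transcripts.
#' @param expression_meanlog,expression_sdlog lognormal baseline abundance
#'   parameters (relative scale; each stage's column is rescaled to
#'   `library_depth`).
#' @param library_depth total tag observations sampled per library.
#' @param base_error_rate per-base substitution probability applied to the
#'   17 variable bases of each sampled tag (the CATG anchor is part of the
#'   library structure and is not corrupted).
#' @param n_contamination_rate probability a sampled observation has one
#'   base masked to N.
#' @param singleton_noise_rate fraction of the library consisting of
#'   unique junk tags (each seen once, so the copy-number filter removes
#'   them).
#' @param guarantee_tag_fraction fraction of unigenes guaranteed to carry
#'   at least one CATG site with 17 nt downstream.
#' @param seed integer seed fixing every downstream draw.
#' @return object of class `sim_config` (validated list of the above).
#' @export
sim_config <- function(n_unigenes = 500,
                       length_range = c(200, 1500),
                       gc_fraction = 0.42,
                       stages = c("egg", "larva", "pupa", "adult"),
                       specific_fraction_per_stage = 0.15,
                       expression_meanlog = 0,
                       expression_sdlog = 1,
                       library_depth = 3.5e6,
                       base_error_rate = 0.001,
                       n_contamination_rate = 0.005,
                       singleton_noise_rate = 0.02,
                       guarantee_tag_fraction = 0.95,
                       seed = 1L) {
  stopifnot(n_unigenes >= 1, length(length_range) == 2)
  if (length_range[[1]] > length_range[[2]])
    stop("sim_config: length_range min exceeds max")
  if (length_range[[1]] < 21)
    stop("sim_config: minimum unigene length must be >= 21 nt")
  if (length(stages) < 1 || anyDuplicated(stages))
    stop("sim_config: stage labels must be unique")
  f <- rep_len(specific_fraction_per_stage, length(stages))
  props <- c(gc_fraction, f, base_error_rate, n_contamination_rate,
             singleton_noise_rate, guarantee_tag_fraction)
  if (any(props < 0 | props > 1))
    stop("sim_config: all proportions must lie in [0, 1]")
  if (sum(f) > 1)
    stop("sim_config: stage-specific fractions sum beyond 1")
  if (library_depth < 1) stop("sim_config: library_depth must be >= 1")
  stopifnot(is.finite(seed), abs(seed) < 2^31)
  structure(list(
    n_unigenes = as.integer(n_unigenes), length_range = as.integer(length_range),
    gc_fraction = gc_fraction, stages = stages,
    specific_fraction_per_stage = f,
    expression_meanlog = expression_meanlog, expression_sdlog = expression_sdlog,
    library_depth = as.integer(library_depth),
    base_error_rate = base_error_rate,
    n_contamination_rate = n_contamination_rate,
    singleton_noise_rate = singleton_noise_rate,
    guarantee_tag_fraction = guarantee_tag_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# stage-scoped sub-seed, kept within 32-bit integer range
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 31 + k) %% 2147483647)

#' Generate a synthetic unigene set
#'
#' Random DNA sequences at the configured GC content and length range.
#' A configured fraction of unigenes has a CATG site with at least 17 nt
#' downstream planted at a random admissible position, guaranteeing a
#' virtual tag; the rest may or may not contain one by chance.
#' Byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @return named character vector of sequences (ids `UN000001`, ...).
#' @export
generate_unigenes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1), {
    n <- config$n_unigenes
    gc <- config$gc_fraction
    base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    span <- config$length_range[[2]] - config$length_range[[1]] + 1L
    lens <- config$length_range[[1]] + sample.int(span, n, replace = TRUE) - 1L
    guaranteed <- stats::runif(n) < config$guarantee_tag_fraction
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(names(base_p), lens[[i]], replace = TRUE, prob = base_p)
      if (guaranteed[[i]]) {
        pos <- sample.int(lens[[i]] - 20L, 1)   # CATG at pos, 17 nt after
        s[pos:(pos + 3L)] <- c("C", "A", "T", "G")
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("UN%06d", seq_len(n))
    seqs
  })
}

#' Ground-truth expression structure
#'
#' Assigns each unigene a specificity label (one stage, or `"shared"`)
#' and a lognormal baseline abundance, then builds the expected tag-count
#' matrix: a stage-specific unigene has nonzero expected count only in its
#' own stage; a shared unigene carries its baseline in every stage. Each
#' stage column is rescaled so its expected total equals `library_depth`.
#' Unigenes without an eligible CATG site cannot produce a tag and are
#' assigned zero expression and label `"none"`.
#'
#' @param config a [sim_config()].
#' @param unigenes the [generate_unigenes()] output (or any named
#'   sequence set).
#' @return object of class `ground_truth`: list with
#'   \describe{
#'     \item{expression}{matrix unigene x stage of expected tag counts.}
#'     \item{labels}{named character vector: stage label, `"shared"`, or
#'       `"none"` (no tag site / not expressed).}
#'     \item{canonical_tag17}{named character vector of each expressed
#'       unigene's canonical 17 nt tag.}
#'     \item{stages}{stage labels.}
#'   }
#' @export
generate_expression_matrix <- function(config, unigenes) {
  stopifnot(inherits(config, "sim_config"), length(unigenes) >= 1)
  ids <- names(unigenes)
  canon <- vapply(seq_along(unigenes), function(i) {
    ct <- canonical_tag(unigenes[[i]], ids[[i]])
    if (is.null(ct)) NA_character_ else ct$tag17
  }, character(1))
  names(canon) <- ids
  eligible <- !is.na(canon)
  with_seed(sub_seed(config$seed, 2), {
    k <- length(config$stages)
    f <- config$specific_fraction_per_stage
    labels <- rep("none", length(ids)); names(labels) <- ids
    labels[eligible] <- sample(c(config$stages, "shared"),
                               sum(eligible), replace = TRUE,
                               prob = c(f, 1 - sum(f)))
    abun <- stats::rlnorm(length(ids), config$expression_meanlog,
                          config$expression_sdlog)
    expr <- matrix(0, length(ids), k, dimnames = list(ids, config$stages))
    for (j in seq_len(k)) {
      on <- labels == config$stages[[j]] | labels == "shared"
      expr[on, j] <- abun[on]
      if (any(on)) expr[, j] <- expr[, j] * config$library_depth / sum(expr[, j])
    }
    structure(list(expression = expr, labels = labels,
                   canonical_tag17 = canon[eligible], stages = config$stages),
              class = "ground_truth")
  })
}

# junk 17-mers that collide with no true tag and with each other
random_junk_tags <- function(n, forbidden) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i)
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""),
      character(1))
    cand <- setdiff(unique(cand), forbidden)
    forbidden <- c(forbidden, cand)
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Sample a raw tag library for one stage
#'
#' Draws `library_depth` raw 21 nt observations for the given stage:
#' a share `singleton_noise_rate` of unique junk tags (random CATG-anchored
#' 17-mers, rejected on collision with any true tag so that the
#' copy-number filter is what removes them), and the remainder a
#' multinomial sample of canonical tags proportional to the stage's
#' expected counts. Each real observation then has its 17 variable bases
#' substituted at `base_error_rate` per base, and with probability
#' `n_contamination_rate` any observation has one variable base masked to
#' N. Output order is a deterministic shuffle under the seed.
#'
#' With `sampling = "expected"` the multinomial draw is replaced by the
#' rounded expected counts (no sampling noise); the emitted depth then
#' equals the sum of rounded counts plus junk.
#'
#' @param truth a [generate_expression_matrix()] result.
#' @param stage stage label to sample.
#' @param config the [sim_config()].
#' @param sampling `"multinomial"` (default) or `"expected"`.
#' @return character vector of raw 21 nt observations.
#' @export
sample_tag_library <- function(truth, stage, config,
                               sampling = c("multinomial", "expected")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(truth, "ground_truth"))
  if (!stage %in% truth$stages) stop("sample_tag_library: unknown stage ", stage)
  depth <- config$library_depth
  if (depth == 0) { warning("depth 0: empty library"); return(character(0)) }
  j <- match(stage, truth$stages)
  with_seed(sub_seed(config$seed, 10 + j), {
    expct <- truth$expression[names(truth$canonical_tag17), j]
    n_junk <- round(depth * config$singleton_noise_rate)
    n_real <- depth - n_junk
    counts <- if (sampling == "multinomial") {
      if (sum(expct) == 0) stop("sample_tag_library: stage has zero total expression")
      as.vector(stats::rmultinom(1, n_real, prob = expct))
    } else {
      round(expct * n_real / sum(expct))
    }
    tags17 <- rep(truth$canonical_tag17, counts)
    n_obs <- length(tags17)
    # substitution errors on the 17 variable bases
    if (config$base_error_rate > 0 && n_obs > 0) {
      nerr <- stats::rbinom(n_obs, 17, config$base_error_rate)
      for (i in which(nerr > 0)) {
        chars <- strsplit(tags17[[i]], "")[[1]]
        pos <- sample.int(17, nerr[[i]])
        for (p in pos)
          chars[[p]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[p]]), 1)
        tags17[[i]] <- paste(chars, collapse = "")
      }
    }
    junk <- if (n_junk > 0)
      random_junk_tags(n_junk, unique(truth$canonical_tag17)) else character(0)
    all17 <- c(tags17, junk)
    # N contamination over the whole library
    if (config$n_contamination_rate > 0 && length(all17)) {
      hit <- which(stats::runif(length(all17)) < config$n_contamination_rate)
      for (i in hit) {
        p <- sample.int(17, 1)
        substr(all17[[i]], p, p) <- "N"
      }
    }
    obs <- paste0("CATG", all17)
    obs[sample.int(length(obs))]
  })
}

#' Simulate a dose-response bioassay
#'
#' Binomial mortality around a probit dose-response curve with natural
#' (control) mortality: `p(d) = c + (1 - c) * pnorm(slope * (log10 d -
#' log10 LC50))`. A dose-0 control row drawn from the same binomial
#' machinery is always included, for Abbott correction downstream.
#'
#' @param true_lc50 true LC50, dose units (> 0).
#' @param probit_slope probit slope per log10 dose (> 0).
#' @param control_mortality natural mortality proportion c, in [0, 1).
#' @param doses positive test doses.
#' @param n_per_dose subjects per dose (recycled; also used for the
#'   control row).
#' @param seed integer seed.
#' @return data.frame `dose` (0 first), `n`, `dead`, `mortality_pct`.
#' @export
simulate_bioassay <- function(true_lc50, probit_slope, control_mortality,
                              doses, n_per_dose, seed = 1L) {
  if (probit_slope <= 0) stop("simulate_bioassay: slope must be positive")
  if (any(doses <= 0)) stop("simulate_bioassay: doses must be positive")
  if (control_mortality < 0 || control_mortality >= 1)
    stop("simulate_bioassay: control mortality must lie in [0, 1)")
  n <- rep_len(n_per_dose, length(doses))
  with_seed(seed, {
    p <- control_mortality + (1 - control_mortality) *
      stats::pnorm(probit_slope * (log10(doses) - log10(true_lc50)))
    dead <- stats::rbinom(length(doses), n, p)
    n0 <- n[[1]]
    dead0 <- stats::rbinom(1, n0, control_mortality)
    out <- data.frame(dose = c(0, doses), n = c(n0, n), dead = c(dead0, dead))
    out$mortality_pct <- 100 * out$dead / out$n
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates replicate Ct records for one gene across samples with
#' programmed fold changes relative to a calibrator:
#' `ct_target = ct_target_calibrator - log2(fold) + noise`, reference-gene
#' Ct constant up to the same Gaussian noise.
#'
#' @param fold_changes named numeric vector of true fold changes per
#'   sample (> 0); the calibrator is added automatically at fold 1.
#' @param gene gene label.
#' @param calibrator calibrator sample label.
#' @param ct_target_calibrator calibrator target-gene Ct.
#' @param ct_reference reference-gene Ct (e.g. 18S rRNA).
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param n_replicates replicates per sample.
#' @param seed integer seed.
#' @return data.frame `sample`, `gene`, `replicate`, `ct_target`,
#'   `ct_reference` suitable for [relative_expression()].
#' @export
simulate_qpcr <- function(fold_changes, gene = "gene1",
                          calibrator = "calibrator",
                          ct_target_calibrator = 24, ct_reference = 15,
                          noise_sd = 0, n_replicates = 3, seed = 1L) {
  if (any(fold_changes <= 0)) stop("simulate_qpcr: fold changes must be positive")
  if (is.null(names(fold_changes)) || !all(nzchar(names(fold_changes))))
    stop("simulate_qpcr: fold_changes must be named by sample")
  folds <- c(stats::setNames(1, calibrator), fold_changes)
  with_seed(seed, {
    rows <- lapply(names(folds), function(s) {
      data.frame(sample = s, gene = gene, replicate = seq_len(n_replicates),
                 ct_target = ct_target_calibrator - log2(folds[[s]]) +
                   stats::rnorm(n_replicates, 0, noise_sd),
                 ct_reference = ct_reference +
                   stats::rnorm(n_replicates, 0, noise_sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
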