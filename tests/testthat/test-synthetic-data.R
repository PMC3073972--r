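test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(length_range = c(500, 100)), "min exceeds max")
  expect_error(sim_config(length_range = c(10, 100)), ">= 21")
  expect_error(sim_config(specific_fraction_per_stage = 0.3), "beyond 1")
  expect_error(sim_config(gc_fraction = 1.2), "proportions")
  expect_error(sim_config(library_depth = 0), "library_depth")
  expect_error(sim_config(stages = c("a", "a")), "unique")
})

test_that("unigene generation is deterministic and honours the tag guarantee", {
  cfg <- sim_config(n_unigenes = 100, seed = 7)
  expect_identical(generate_unigenes(cfg), generate_unigenes(cfg))

  # fixed 25 nt sequence with a guaranteed site: CATG must start by offset 4
  cfg1 <- sim_config(n_unigenes = 1, length_range = c(25, 25),
                     guarantee_tag_fraction = 1, seed = 1)
  u1 <- generate_unigenes(cfg1)
  pos <- regexpr("CATG", u1[[1]], fixed = TRUE)
  expect_lte(as.integer(pos) - 1, 4)
  expect_gte(nchar(u1[[1]]) - (as.integer(pos) + 3), 17)

  cfg2 <- sim_config(n_unigenes = 200, guarantee_tag_fraction = 1, seed = 3)
  u2 <- generate_unigenes(cfg2)
  idx <- build_tag_index(u2, mode = "all")
  expect_length(idx$unigenes_without_sites, 0)
  expect_true(all(grepl("^[ACGT]+$", u2)))
})

test_that("ground truth separates stage-specific from shared expression", {
  cfg <- sim_config(n_unigenes = 300, specific_fraction_per_stage = 0.2,
                    guarantee_tag_fraction = 1, library_depth = 1e5, seed = 12)
  u <- generate_unigenes(cfg)
  tr <- generate_expression_matrix(cfg, u)
  expect_identical(tr$expression,
                   generate_expression_matrix(cfg, u)$expression)
  for (s in cfg$stages) {
    spec <- names(tr$labels)[tr$labels == s]
    other <- setdiff(cfg$stages, s)
    expect_true(all(tr$expression[spec, other] == 0))
    expect_true(all(tr$expression[spec, s] > 0))
  }
  shared <- names(tr$labels)[tr$labels == "shared"]
  expect_true(all(tr$expression[shared, ] > 0))
  # stage columns scale to the library depth expectation
  expect_equal(unname(colSums(tr$expression)), rep(1e5, 4))
  # every expressed unigene has a recorded canonical tag
  expressed <- rownames(tr$expression)[rowSums(tr$expression) > 0]
  expect_true(all(expressed %in% names(tr$canonical_tag17)))
})

test_that("specificity labels follow the configured multinomial fractions", {
  cfg <- sim_config(n_unigenes = 1000, specific_fraction_per_stage = 0.25,
                    guarantee_tag_fraction = 1, seed = 5)
  tr <- generate_expression_matrix(cfg, generate_unigenes(cfg))
  counts <- table(factor(tr$labels, levels = cfg$stages))
  band <- stats::qbinom(c(0.005, 0.995), 1000, 0.25)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("tag libraries conserve depth and corrupt at the configured rates", {
  cfg <- sim_config(n_unigenes = 60, library_depth = 1e5,
                    base_error_rate = 0.001, n_contamination_rate = 0.005,
                    singleton_noise_rate = 0.02, guarantee_tag_fraction = 1,
                    seed = 13)
  u <- generate_unigenes(cfg)
  tr <- generate_expression_matrix(cfg, u)
  obs <- sample_tag_library(tr, "pupa", cfg)
  expect_length(obs, 1e5)
  expect_identical(obs, sample_tag_library(tr, "pupa", cfg))
  expect_true(all(nchar(obs) == 21))
  expect_true(all(startsWith(obs, "CATG")))
  # N contamination within 3 sigma of its binomial expectation
  p <- cfg$n_contamination_rate
  n_n <- sum(grepl("N", obs, fixed = TRUE))
  expect_lt(abs(n_n - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)))

  # no corruption path: every observation is a true canonical tag
  cfg0 <- sim_config(n_unigenes = 60, library_depth = 5000,
                     base_error_rate = 0, n_contamination_rate = 0,
                     singleton_noise_rate = 0, guarantee_tag_fraction = 1,
                     seed = 13)
  tr0 <- generate_expression_matrix(cfg0, generate_unigenes(cfg0))
  obs0 <- sample_tag_library(tr0, "egg", cfg0)
  expect_true(all(obs0 %in% paste0("CATG", tr0$canonical_tag17)))

  # total contamination: the filter calls everything low quality
  cfgN <- sim_config(n_unigenes = 60, library_depth = 2000,
                     n_contamination_rate = 1, guarantee_tag_fraction = 1,
                     seed = 13)
  trN <- generate_expression_matrix(cfgN, generate_unigenes(cfgN))
  obsN <- sample_tag_library(trN, "egg", cfgN)
  accN <- filter_tags(obsN, library_label = "egg")$accounting
  expect_equal(accN$lowq_total, accN$raw_total)
  expect_equal(accN$clean_total, 0)

  expect_error(sample_tag_library(tr, "embryo", cfg), "unknown stage")
})

test_that("bioassay simulation follows the probit-with-control model", {
  expect_error(simulate_bioassay(60, -1, 0, 10, 10), "slope")
  expect_error(simulate_bioassay(60, 4, 1, 10, 10), "control mortality")
  expect_error(simulate_bioassay(60, 4, 0, c(-5, 10), 10), "positive")

  # near-step dose-response: double the LC50 kills everything
  a <- simulate_bioassay(60, 50, 0, 120, 1000, seed = 2)
  expect_equal(a$dead[a$dose == 120], 1000)
  # at the LC50 with no control mortality: 50% within 3 sigma
  b <- simulate_bioassay(60, 4, 0, 60, 1e6, seed = 2)
  expect_lt(abs(b$dead[b$dose == 60] - 5e5), 3 * sqrt(1e6 * 0.25))
  # dose-0 control row is always present
  expect_true(0 %in% a$dose)
  expect_identical(a, simulate_bioassay(60, 50, 0, 120, 1000, seed = 2))
})

test_that("qPCR simulation encodes fold changes in target Ct", {
  ct <- simulate_qpcr(c(s1 = 4), noise_sd = 0, seed = 9)
  expect_error(simulate_qpcr(c(s1 = -2)), "positive")
  cal <- ct[ct$sample == "calibrator", ]
  s1 <- ct[ct$sample == "s1", ]
  expect_equal(unique(s1$ct_target), unique(cal$ct_target) - 2) # -log2(4)
  expect_equal(unique(s1$ct_reference), unique(cal$ct_reference))
  expect_identical(ct, simulate_qpcr(c(s1 = 4), noise_sd = 0, seed = 9))
})
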