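stages4 <- c("egg", "larva", "pupa", "adult")

test_that("mapping credits unique tags, tallies ambiguous and unmapped", {
  counts <- rbind(c(0, 3281, 0, 0),   # confined to larva
                  c(8, 2244, 0, 8),
                  c(0, 6325, 1942, 1136))
  colnames(counts) <- stages4
  fx <- profile_fixture(counts)
  pr <- fx$profile
  expect_equal(unname(unlist(pr$unigene_counts[pr$unigene_counts$unigene_id == "G001",
                                               stages4])),
               c(0, 3281, 0, 0))
  # conservation identity per stage
  expect_equal(pr$mapped_unique + pr$ambiguous + pr$unmapped, pr$clean_total)
  expect_equal(unname(pr$unmapped), rep(0, 4))

  # a clean tag absent from the index is counted unmapped, credits nothing
  stray <- data.frame(tag17 = random_tag17(1), count = 5L)
  clean2 <- fx$clean
  clean2$larva <- rbind(clean2$larva, stray)
  pr2 <- map_tags(clean2, fx$index)
  expect_equal(unname(pr2$unmapped["larva"]), 5)
  expect_equal(pr2$unigene_counts, pr$unigene_counts)

  # ambiguous tags never reach unigene counts
  tag <- random_tag17(1)
  dup <- c(a = paste0("CATG", tag), b = paste0(strrep("T", 20), "CATG", tag))
  idx2 <- build_tag_index(dup)
  cl <- list(egg = data.frame(tag17 = tag, count = 10L))
  pr3 <- map_tags(cl, idx2)
  expect_equal(unname(pr3$ambiguous["egg"]), 10)
  expect_equal(nrow(pr3$unigene_counts), 0)

  expect_error(map_tags(unname(fx$clean), fx$index), "named")
})

test_that("copy-number binning matches a brute-force histogram and the bin grammar", {
  cl <- list(x = data.frame(tag17 = random_tag17(1), count = 2L))
  cn <- copy_number_distribution(cl)
  expect_equal(cn$x[cn$bin == "2"], 1)
  expect_equal(sum(cn$x[cn$bin != "Total"]), 1)

  set.seed(17)
  counts <- sample(2:20000, 400, replace = TRUE)
  cl2 <- list(y = data.frame(tag17 = random_tag17(400), count = counts))
  bins <- default_copy_number_bins()
  got <- copy_number_distribution(cl2)$y
  brute <- vapply(seq_along(bins), function(i) {
    hi <- if (i < length(bins)) bins[i + 1] - 1 else Inf
    sum(counts >= bins[i] & counts <= hi)
  }, numeric(1))
  expect_equal(got[seq_along(bins)], brute)
  expect_equal(got[length(bins) + 1], 400) # total row equals clean_unique

  expect_error(copy_number_distribution(cl, bins = c(3, 10)), "starting at 2")
  expect_error(copy_number_distribution(cl, bins = c(2, 2, 10)), "strictly increasing")
  expect_error(copy_number_distribution(list(x = data.frame(tag17 = "A", count = 1L))),
               "copy number < 2")
})

test_that("published copy-number table margins are internally consistent", {
  tab <- acb_copy_number()
  expect_equal(colSums(tab[stages4]),
               c(egg = 71004, larva = 71228, pupa = 89637, adult = 89116))
  expect_equal(sum(tab[stages4]), 320985)
})

test_that("venn partition is disjoint and exhaustive over detected items", {
  counts <- rbind(c(0, 50, 0, 0), c(0, 12, 0, 0),   # larva only
                  c(2, 2, 2, 2))                    # everywhere
  colnames(counts) <- stages4
  fx <- profile_fixture(counts)
  vt <- venn_partition(fx$profile, "unigene")
  expect_equal(vt$count[vt$category == "larva"], 2)
  expect_equal(vt$count[vt$category == "egg&larva&pupa&adult"], 1)
  expect_equal(sum(vt$count), 3)
  expect_equal(nrow(vt), 15)

  # against a brute-force subset enumeration on random presence patterns
  set.seed(23)
  m <- matrix(sample(c(0, 2, 7), 10 * 4, replace = TRUE), 10, 4,
              dimnames = list(NULL, stages4))
  m[rowSums(m) == 0, 1] <- 2
  fx2 <- profile_fixture(m)
  vt2 <- venn_partition(fx2$profile, "unigene")
  for (i in seq_len(nrow(vt2))) {
    members <- strsplit(vt2$category[i], "&", fixed = TRUE)[[1]]
    expected <- sum(apply(m > 0, 1, function(r)
      setequal(stages4[r], members)))
    expect_equal(vt2$count[i], expected)
  }
})

test_that("strict and dominance modes implement the published call semantics", {
  tab <- acb_target_tags()
  counts <- as.matrix(tab[stages4])
  fx <- profile_fixture(counts, tags = tab$tag17)
  pr <- fx$profile

  strict <- stage_specific_calls(pr, "strict", min_count = 100)
  strict_tags <- strict$tag17
  # DS5-pattern (0, 3281, 0, 0): strict larval call
  expect_true(tab$tag17[tab$name == "DS5"] %in% strict_tags)
  # DS6-pattern (8, 2244, 0, 8): rejected by strict, passes dominance >= 10
  expect_false(tab$tag17[tab$name == "DS6"] %in% strict_tags)
  dom10 <- stage_specific_calls(pr, "dominance", min_count = 100,
                                fold_threshold = 10)
  ds6 <- dom10[dom10$tag17 == tab$tag17[tab$name == "DS6"], ]
  expect_equal(ds6$called_stage, "larva")
  expect_equal(ds6$fold_dominance, 2244 / 8)
  # DS2-pattern (0, 6325, 1942, 1136): fold 3.257 -> in at 3, out at 5
  ds2tag <- tab$tag17[tab$name == "DS2"]
  dom3 <- stage_specific_calls(pr, "dominance", min_count = 100, fold_threshold = 3)
  dom5 <- stage_specific_calls(pr, "dominance", min_count = 100, fold_threshold = 5)
  expect_true(ds2tag %in% dom3$tag17)
  expect_false(ds2tag %in% dom5$tag17)
  expect_equal(dom3$fold_dominance[dom3$tag17 == ds2tag], 6325 / 1942)

  # strict calls are a subset of dominance calls at any finite threshold
  expect_true(all(strict$tag17 %in% dom10$tag17))
  expect_error(stage_specific_calls(pr, "dominance", fold_threshold = 1), "exceed 1")
  expect_error(stage_specific_calls(pr, min_count = 0), "min_count")
})

test_that("target ranking orders by called-stage count with lexicographic ties", {
  tab <- acb_target_tags()
  fx <- profile_fixture(as.matrix(tab[stages4]), tags = tab$tag17)
  calls <- stage_specific_calls(fx$profile, "dominance", min_count = 100,
                                fold_threshold = 3)
  ranked <- rank_targets(calls, "larva")
  expect_equal(ranked$tag17[1], tab$tag17[tab$name == "DS2"])   # 6325 first
  expect_equal(ranked$tag17[nrow(ranked)], tab$tag17[tab$name == "DS35"]) # 390 last
  expect_equal(nrow(rank_targets(calls, "larva", top_k = 1)), 1)
  expect_error(rank_targets(calls, "embryo"), "no calls")

  tied <- rbind(c(0, 500, 0, 0), c(0, 500, 0, 0))
  colnames(tied) <- stages4
  fx2 <- profile_fixture(tied, tags = c("TTTTTTTTTTTTTTTTT", "AAAAAAAAAAAAAAAAA"))
  r2 <- rank_targets(stage_specific_calls(fx2$profile, "strict", min_count = 10),
                     "larva")
  expect_equal(r2$tag17, c("AAAAAAAAAAAAAAAAA", "TTTTTTTTTTTTTTTTT"))
})

test_that("tags-per-million sums to one million", {
  one <- tags_per_million(data.frame(tag17 = "X", count = 7L))
  expect_equal(one$tpm, 1e6)
  two <- tags_per_million(data.frame(tag17 = c("a", "b"), count = c(2L, 2L)))
  expect_equal(two$tpm, c(5e5, 5e5))
  set.seed(4)
  many <- tags_per_million(data.frame(tag17 = random_tag17(200),
                                      count = sample(2:5000, 200)))
  expect_equal(sum(many$tpm), 1e6, tolerance = 1e-9)
  expect_error(tags_per_million(data.frame(tag17 = character(), count = integer())),
               "empty")
})
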