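test_that("downscaling keeps the first image of each case, in natural order", {
  profs <- toy_profiles(n_cases = 4, labels = c("LA", "CLL"),
                        images_per_case = 3, seed = 2)
  one <- downscale_first_image(profs)
  expect_equal(nrow(one), 8L)
  expect_true(all(one$image_id == "s1"))
  # natural order: s2 precedes s10
  odd <- profs[profs$case_id == "LA_c01", ][1:2, ]
  odd$image_id <- c("s10", "s2")
  expect_equal(downscale_first_image(odd)$image_id, "s2")
  # idempotence
  expect_equal(downscale_first_image(one), one)
  # explicit ordering column overrides
  odd$section_order <- c(1, 2)
  expect_equal(downscale_first_image(odd, order_col = "section_order")$image_id,
               "s10")
})

test_that("the full-cohort table downscales to one profile per case", {
  co <- simulate_cohort_profiles(1, seed = 12)
  one <- downscale_first_image(co)
  expect_equal(nrow(one), 82L)
  expect_equal(anyDuplicated(one$case_id), 0L)
})

test_that("stratified train sizes honour the rounding and clamping rules", {
  expect_equal(macropath:::stratified_train_size(9L, 0.75), 7L)    # 6.75 -> 7
  expect_equal(macropath:::stratified_train_size(10L, 0.75), 8L)   # 7.5 -> 8
  expect_equal(macropath:::stratified_train_size(2L, 0.75), 1L)    # keep a test case
  expect_equal(macropath:::stratified_train_size(3L, 0.05), 1L)    # keep a train case
})

test_that("perfectly separated classes are classified almost perfectly", {
  profs <- toy_profiles(n_cases = 20, labels = c("LA", "CLL"),
                        images_per_case = 1, seed = 7)
  # disjoint supports: shift every feature of one class far away
  shift <- profs$diagnosis == "CLL"
  for (f in feature_registry()) profs[[f]][shift] <- profs[[f]][shift] + 1e3
  dr <- run_diversity(profs, diversity_config(n_iterations = 40, seed = 5))
  expect_true(all(diag(dr$confusion_pct) >= 95))
  expect_true(all(dr$auc >= 0.99))
})

test_that("confusion counts conserve test appearances exactly", {
  profs <- toy_profiles(n_cases = 8, labels = c("LA", "CLL", "FL"),
                        images_per_case = 1, seed = 3)
  dr <- run_diversity(profs, diversity_config(n_iterations = 25, seed = 11))
  expect_equal(unname(rowSums(dr$confusion_counts)),
               unname(dr$test_appearances))
  # percentages recover counts exactly
  recovered <- sweep(dr$confusion_pct / 100, 1, dr$test_appearances, "*")
  expect_equal(unname(recovered), unname(unclass(dr$confusion_counts)))
  expect_true(all(abs(rowSums(dr$confusion_pct) - 100) < 1e-9))
})

test_that("identical seeds reproduce the whole result bitwise", {
  profs <- toy_profiles(n_cases = 6, labels = c("LA", "DLBCL"),
                        images_per_case = 1, seed = 9)
  cfg <- diversity_config(n_iterations = 10, seed = 21)
  a <- run_diversity(profs, cfg)
  b <- run_diversity(profs, cfg)
  expect_identical(a$confusion_counts, b$confusion_counts)
  expect_identical(a$auc, b$auc)
  expect_identical(a$roc, b$roc)
  c_ <- run_diversity(profs, diversity_config(n_iterations = 10, seed = 22))
  expect_false(identical(a$confusion_counts, c_$confusion_counts))
})

test_that("every stratified training split contains every class", {
  profs <- toy_profiles(n_cases = 4, labels = c("LA", "CLL", "FL", "MCcHL"),
                        images_per_case = 1, seed = 15)
  y <- factor(profs$diagnosis)
  cfg <- diversity_config(train_fraction = 0.6, seed = 2)
  withr::with_seed(1, {
    for (i in 1:50) {
      tr <- macropath:::draw_split(y, cfg)
      expect_setequal(as.character(unique(y[tr])), levels(y))
    }
  })
})

test_that("imputation is fitted on the training fold only", {
  profs <- toy_profiles(n_cases = 8, labels = c("LA", "CLL"),
                        images_per_case = 1, seed = 4)
  x <- as.data.frame(profs[, feature_registry()])
  y <- factor(profs$diagnosis)
  x$cd163_volume[2] <- NA          # a hole the imputer must fill
  train_idx <- c(1:6, 9:14)
  base <- diversity_split_fit(x, y, train_idx, diversity_config(seed = 1))
  # plant a sentinel outlier in the *test* fold: training-side statistics
  # and predictions must not move at all
  x2 <- x
  test_rows <- setdiff(seq_len(nrow(x2)), train_idx)
  x2$cd68_volume[test_rows[1]] <- 1e9
  withr::with_seed(99, {
    poked <- diversity_split_fit(x2, y, train_idx, diversity_config(seed = 1))
  })
  expect_identical(base$imputer$values, poked$imputer$values)
  # the training medians come from training rows only
  expect_equal(unname(base$imputer$values["cd68_volume"]),
               median(x$cd68_volume[train_idx]))
})

test_that("permuted balanced labels classify at chance level", {
  # one data draw pins persistent accidental structure, so the null is
  # evaluated as an average over independent label permutations
  one <- downscale_first_image(simulate_cohort_profiles(0, seed = 5))
  reps <- withr::with_seed(31, lapply(1:3, function(i) {
    one$diagnosis <- sample(rep_len(pathomic_entities(), nrow(one)))
    run_diversity(one, diversity_config(n_iterations = 40, seed = 8 + i,
                                        downscale = FALSE))
  }))
  diag_mean <- mean(vapply(reps, function(r) mean(diag(r$confusion_pct)),
                           numeric(1)))
  auc_mean <- mean(vapply(reps, function(r) mean(r$auc), numeric(1)))
  expect_lt(abs(diag_mean - 100 / 6), 7)
  expect_gt(auc_mean, 0.4); expect_lt(auc_mean, 0.6)
})

test_that("attribution finds a planted signal and zeroes constants", {
  profs <- toy_profiles(n_cases = 30, labels = c("LA", "CLL"),
                        images_per_case = 1, seed = 18)
  # neutralize all real differences, then plant one informative feature
  for (f in feature_registry()) profs[[f]] <- rnorm(nrow(profs))
  profs$cd68_volume <- ifelse(profs$diagnosis == "CLL", 5, -5) +
    rnorm(nrow(profs), 0, 0.1)
  profs$estrada_index <- 1.0  # constant
  att <- feature_attribution(profs, diversity_config(seed = 6, n_trees = 50),
                             n_repeats = 5)
  expect_equal(att$feature[1], "cd68_volume")
  expect_equal(att$attribution[att$feature == "estrada_index"], 0)
  # determinism
  att2 <- feature_attribution(profs, diversity_config(seed = 6, n_trees = 50),
                              n_repeats = 5)
  expect_identical(att, att2)
})

test_that("pure-noise features stay below a permutation-derived bound", {
  withr::with_seed(27, {
    profs <- toy_profiles(n_cases = 24, labels = c("LA", "CLL"),
                          images_per_case = 1, seed = 25)
    for (f in feature_registry()) profs[[f]] <- rnorm(nrow(profs))
    att <- feature_attribution(profs, diversity_config(seed = 7, n_trees = 50),
                               n_repeats = 5)
    # null calibration: refit with freshly permuted labels
    null_max <- vapply(1:3, function(i) {
      p2 <- profs
      p2$diagnosis <- sample(p2$diagnosis)
      max(feature_attribution(p2, diversity_config(seed = 7 + i, n_trees = 50),
                              n_repeats = 5)$attribution)
    }, numeric(1))
    expect_lt(max(att$attribution), 2 * max(null_max))
  })
})

test_that("degenerate class layouts are rejected", {
  profs <- toy_profiles(n_cases = 4, labels = c("LA", "CLL"),
                        images_per_case = 1, seed = 2)
  expect_error(run_diversity(profs[profs$diagnosis == "LA", ]), ">= 2 classes")
  solo <- profs[c(which(profs$diagnosis == "LA"),
                  which(profs$diagnosis == "CLL")[1]), ]
  expect_error(run_diversity(solo), "CLL")
})
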