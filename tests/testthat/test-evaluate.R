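test_that("LOOCV bookkeeping: one fold per trial, mean of folds", {
  trials <- simulate_coupled_subject(21)
  spec <- narx_ground_truth_process()$spec
  sc <- loocv_score(trials, spec, control = narx_control(n_units = 0))
  expect_length(sc$fold_r, 7)
  expect_equal(sc$mean_r, mean(sc$fold_r))
})

test_that("identical trials give identical fold correlations", {
  tab <- toy_feature_table(80, features = "u1")
  spec <- lag_spec(1, "u1", 1, 1)
  proc <- true_narx_process(spec, a = 0.5, b_lin = list(c(0.3, 0.1)),
                            noise_sd = 0)
  tab$intensity <- generate_intensity_from_narx(tab, proc, seed = 1)$y_raw
  trials <- replicate(4, feature_set(tab, 2.56), simplify = FALSE)
  sc <- loocv_score(trials, spec, control = narx_control(n_units = 0))
  expect_equal(max(sc$fold_r) - min(sc$fold_r), 0, tolerance = 1e-10)
})

test_that("the paired Wilcoxon comparison behaves at its edge cases", {
  x <- c(0.5, 0.6, 0.7, 0.55, 0.62, 0.58)
  expect_equal(compare_models(x, x)$p_value, 1)
  # uniform shift with n = 21: the minimal attainable two-sided exact p
  y <- withr::with_seed(1, runif(21, 0.2, 0.4))
  res <- compare_models(y + 0.3, y)
  expect_equal(res$p_value, 2 / 2^21, tolerance = 1e-12)
  expect_warning(compare_models(c(1, 2), c(0, 1)), "low power")
})

test_that("the signed-rank statistic matches a manual implementation", {
  manual_V <- function(d) {
    d <- d[d != 0]
    sum(rank(abs(d))[d > 0])
  }
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- rnorm(15)
      b <- rnorm(15)
      expect_equal(compare_models(a, b)$statistic, manual_V(a - b))
    }
  })
})

test_that("feature ranking counts one occurrence per subject", {
  sets <- tibble::tibble(
    quality = "Q1", model_kind = "narx",
    subject = c("a", "b", "c"),
    features = list(c("hr_filtered", "rsp_rate"),
                    c("hr_filtered", "hr_filtered"), # duplicates collapse
                    "gsr_deriv")
  )
  rk <- rank_features(sets)
  expect_equal(rk$count[rk$feature == "hr_filtered"], 2)
  expect_equal(rk$count[rk$feature == "rsp_rate"], 1)
  expect_equal(sum(rk$count), 4)
})

test_that("median/MAD summaries use the unscaled MAD", {
  s <- summary_stats(c(2, 5, 8)) # symmetric triple
  expect_equal(s$median, 5)
  expect_equal(s$mad, 3)
  one <- summary_stats(0.42)
  expect_equal(one$median, 0.42)
  expect_equal(one$mad, 0)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("Apriori respects the subset-closure property", {
  trans <- list(c("a", "b"), c("a", "b"), c("a", "b", "c"), "c")
  fs <- apriori_frequent_sets(trans, min_support = 2, max_k = 3)
  expect_setequal(fs$itemset[fs$k == 1], c("a", "b", "c"))
  expect_equal(fs$itemset[fs$k == 2], "a+b")
  expect_equal(fs$support[fs$itemset == "a+b"], 3)
  # every subset of a reported frequent itemset is itself reported
  for (row in which(fs$k == 2)) {
    for (it in fs$items[[row]]) {
      expect_true(it %in% fs$itemset[fs$k == 1])
    }
  }
  # all subjects sharing a pair makes it frequent at any threshold <= n
  shared <- replicate(5, c("x", "y"), simplify = FALSE)
  fs2 <- apriori_frequent_sets(shared, min_support = 5)
  expect_setequal(fs2$itemset, c("x", "y", "x+y"))
})

test_that("intersubject evaluation splits, seeds and records its mode", {
  # 6-subject miniature population sharing the generating process
  proc <- narx_ground_truth_process(n_k = c(2L, 2L), bounds = c(1L, 3L))
  dataset <- purrr::map_dfr(1:6, function(s) {
    trials <- simulate_coupled_subject(300 + s, process = proc,
                                       subject = sprintf("S%02d", s))
    tibble::tibble(subject = sprintf("S%02d", s),
                   trial = seq_along(trials), features = trials)
  })
  ga <- ga_config(5, pop_size = 8, max_generations = 4, stall_window = 3)
  expect_warning(
    res <- intersubject_evaluate(dataset, c("gsr_filtered", "rsp_rate"),
                                 repeats = 2, seed = 5, bounds = c(1L, 3L),
                                 ga = ga),
    "proportional"
  )
  expect_equal(nrow(res), 2)
  expect_true(all(res$mode == "paper"))
  for (i in 1:2) {
    expect_length(intersect(res$train[[i]], res$test[[i]]), 0)
    expect_equal(length(res$train[[i]]) + length(res$test[[i]]), 6)
    expect_equal(res$n_train_trials[i], 7 * length(res$train[[i]]))
  }
  expect_suppress <- suppressWarnings
  res2 <- expect_suppress(
    intersubject_evaluate(dataset, c("gsr_filtered", "rsp_rate"),
                          repeats = 2, seed = 5, bounds = c(1L, 3L),
                          ga = ga))
  expect_identical(res$mean_r, res2$mean_r) # seeded determinism
  # the leakage-free mode reports on untouched test subjects
  res3 <- expect_suppress(
    intersubject_evaluate(dataset, c("gsr_filtered", "rsp_rate"),
                          repeats = 1, seed = 5, mode = "holdout",
                          bounds = c(1L, 3L), ga = ga))
  expect_equal(res3$mode, "holdout")
  expect_gt(res3$mean_r, 0.5) # homogeneous population is recoverable
})
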