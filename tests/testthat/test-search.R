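test_that("exhaustive search finds analytic optima and applies the tie-break", {
  ev <- function(p) -(p[1] - 3)^2 - (p[2] - 5)^2 - (p[3] - 7)^2
  res <- exhaustive_lag_search(ev)
  expect_equal(res$par, c(3L, 5L, 7L))
  expect_equal(res$score, 0)
  expect_equal(res$n_eval, 11^3) # 1331 evaluations exactly
  # constant evaluator: lexicographically smallest spec wins
  flat <- exhaustive_lag_search(function(p) 1)
  expect_equal(flat$par, c(1L, 1L, 1L))
  # failures score as -Inf and are logged
  half <- exhaustive_lag_search(function(p) {
    if (p[1] > 5) stop("boom") else -sum(p)
  })
  expect_equal(half$par, c(1L, 1L, 1L))
  expect_gt(length(half$failures), 0)
})

test_that("the generation cap follows the 200-per-parameter rule", {
  expect_equal(ga_config(5)$max_generations, 1000)
  expect_equal(ga_config(7)$max_generations, 1400)
})

test_that("the GA finds a certified integer optimum on most seeds", {
  # separable quadratic with known optimum; certified by construction
  target <- c(2, 9, 4, 11, 6, 1, 8)
  ev <- function(p) -sum((p - target)^2)
  hits <- vapply(1:10, function(s) {
    res <- ga_lag_search(ev, 7, config = ga_config(7, pop_size = 40),
                         seed = s)
    identical(res$par, as.integer(target))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("GA runs are reproducible and logged per generation", {
  ev <- function(p) -sum((p - c(3, 3, 3, 3, 3))^2)
  cfg <- ga_config(5, pop_size = 20, max_generations = 30, stall_window = 10)
  a <- ga_lag_search(ev, 5, config = cfg, seed = 4)
  b <- ga_lag_search(ev, 5, config = cfg, seed = 4)
  expect_identical(a$generations, b$generations)
  expect_identical(a$par, b$par)
  expect_true(all(c("generation", "best", "mean", "sd",
                    "constraint_violation") %in% names(a$generations)))
  expect_true(all(a$generations$constraint_violation == 0))
  expect_true(all(diff(a$generations$best) >= 0)) # best-ever is monotone
})

test_that("GA agrees with exhaustive search on a small shared grid", {
  ev <- function(p) sin(p[1]) + cos(2 * p[2]) + 0.3 * p[3]
  ex <- exhaustive_lag_search(ev, bounds = c(1L, 3L))
  ga <- ga_lag_search(ev, 3, config = ga_config(3, pop_size = 30,
                                                max_generations = 60),
                      bounds = c(1L, 3L), seed = 2)
  expect_equal(ga$score, ex$score, tolerance = 1e-12)
})

test_that("forward selection follows the greedy path of a score table", {
  # hand-simulated greedy path over 4 candidates
  score_table <- c(
    "gsr_filtered" = 0.50, "hr_filtered" = 0.40, "rsp_rate" = 0.30,
    "gsr_deriv" = 0.20,
    "gsr_filtered+hr_filtered" = 0.52, "gsr_filtered+rsp_rate" = 0.60,
    "gsr_deriv+gsr_filtered" = 0.55,
    "gsr_filtered+hr_filtered+rsp_rate" = 0.58,
    "gsr_deriv+gsr_filtered+rsp_rate" = 0.65
  )
  ev <- function(feats) score_table[[paste(sort(feats), collapse = "+")]]
  trace <- forward_feature_selection(
    c("gsr_filtered", "hr_filtered", "rsp_rate", "gsr_deriv"), ev)
  # greedy: gsr_filtered (0.50) -> +rsp_rate (0.60) -> +gsr_deriv (0.65)
  expect_equal(trace$feature_added, c("gsr_filtered", "rsp_rate", "gsr_deriv"))
  expect_equal(trace$score, c(0.50, 0.60, 0.65))
  expect_equal(attr(trace, "stop_reason"), "max features")
})

test_that("the improvement threshold stops the selection", {
  scores <- c("gsr_filtered" = 0.50, "hr_filtered" = 0.40,
              "rsp_rate" = 0.30,
              "gsr_filtered+hr_filtered" = 0.505,
              "gsr_filtered+rsp_rate" = 0.502)
  ev <- function(feats) scores[[paste(sort(feats), collapse = "+")]]
  trace <- forward_feature_selection(
    c("gsr_filtered", "hr_filtered", "rsp_rate"), ev)
  expect_equal(nrow(trace), 1)
  expect_equal(trace$feature_added, "gsr_filtered")
  expect_match(attr(trace, "stop_reason"), "improvement below")
  # accepted features are never revisited or removed
  expect_equal(trace$features[[1]], "gsr_filtered")
})

test_that("score ties break by the canonical feature order", {
  ev <- function(feats) 1 # everything ties
  trace <- forward_feature_selection(
    c("expiration_time", "gsr_filtered", "hr_filtered"), ev, max_k = 1)
  expect_equal(trace$feature_added, "gsr_filtered") # first in canonical order
  expect_error(forward_feature_selection(character(0), ev), "empty")
})
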