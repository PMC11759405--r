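test_that("derivative matches analytic slopes", {
  fs <- 256
  ramp <- 2 * seq(0, 1, length.out = 257) # slope 2 units/s at 256 Hz
  d <- derivative(ramp, 256 / 1) * (256 / 256)
  expect_equal(derivative(2 * (0:256) / 256, 256), rep(2, 257),
               tolerance = 1e-9)
  expect_equal(derivative(rep(5, 100), fs), rep(0, 100))
  tt <- seq(0, 10, by = 1 / fs)
  s <- sin(2 * pi * 0.1 * tt)
  expect_equal(max(abs(derivative(s, fs))), 2 * pi * 0.1, tolerance = 1e-3)
  expect_error(derivative(c(1, 2), fs), "3 samples")
})

test_that("running rate is zero for constants and reacts to steps", {
  fs <- 10
  const <- rep(7, 500)
  expect_true(all(running_rate(const, fs) == 0))
  # step 1 -> 2: once the evaluation window has cleared the step and the
  # reference still sits at 1, the rate approaches (2 - 1) / 1 = +1
  x <- c(rep(1, 300), rep(2, 200))
  rr <- running_rate(x, fs)
  expect_equal(max(rr), 1, tolerance = 0.01)
  # magnitude invariance under sign flip (reference enters as |mean|)
  rr_neg <- running_rate(-x, fs)
  expect_equal(abs(rr_neg), abs(rr), tolerance = 1e-9)
})

test_that("breath segmentation recovers analytic sinusoid cycles", {
  fs <- 64
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rsp <- sin(2 * pi * 0.25 * tt) # 15 breaths/min, period 4 s
  cycles <- breath_segmentation(rsp, fs)
  expect_gt(nrow(cycles), 10)
  expect_equal(median(cycles$inspiration_time), 2, tolerance = 0.05)
  expect_equal(median(cycles$expiration_time), 2, tolerance = 0.05)
  expect_equal(median(cycles$inhalation_depth), 2, tolerance = 0.05)
  expect_equal(median(cycles$rate_bpm), 15, tolerance = 0.1)
  # doubled amplitude doubles depths, leaves timing unchanged
  cycles2 <- breath_segmentation(2 * rsp, fs)
  expect_equal(median(cycles2$inhalation_depth), 4, tolerance = 0.1)
  expect_equal(median(cycles2$inspiration_time), 2, tolerance = 0.05)
  # noise below an absolute prominence threshold yields no cycles
  noise <- withr::with_seed(1, rnorm(length(tt), sd = 1e-4))
  expect_equal(nrow(breath_segmentation(noise, fs, min_prominence = 0.01)), 0)
  # a dead-flat channel yields none under the adaptive default either
  expect_equal(nrow(breath_segmentation(rep(0, length(tt)), fs)), 0)
})

test_that("breath features sample-and-hold between cycle ends", {
  # two-cycle pattern: periods 4 s then 6 s -> rate steps from 15 to 10 bpm
  cycles <- tibble::tibble(
    t_trough = c(0, 4), t_peak = c(2, 7), t_next_trough = c(4, 10),
    inspiration_time = c(2, 3), expiration_time = c(2, 3),
    inhalation_depth = c(1, 1), exhalation_depth = c(1, 1),
    rate_bpm = c(15, 10)
  )
  fs <- 2
  out <- breath_features(cycles, n = 24, fs = fs)
  tt <- (seq_len(24) - 1) / fs
  expect_true(all(out$rsp_rate[tt < 4] == 15))
  expect_true(all(out$rsp_rate[tt >= 4 & tt < 10] == 15 |
                    tt[tt >= 4 & tt < 10] >= 4))
  expect_equal(out$rsp_rate[tt >= 10], rep(10, sum(tt >= 10)))
  expect_equal(unique(out$rsp_rate), c(15, 10))
  # empty cycle list -> NA sentinels
  empty <- breath_features(cycles[0, ], n = 5, fs = fs)
  expect_true(all(is.na(empty$rsp_rate)))
})

test_that("heart-rate extraction recovers constant and ramping rates", {
  fs <- 256
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  mk_pulse <- function(bpm) exp(3 * (cos(2 * pi * cumsum(bpm / 60) / fs) - 1))
  hr <- heart_rate_series(mk_pulse(rep(60, length(tt))), fs)
  expect_false(is.null(hr))
  expect_true(all(abs(hr - 60) < 1))
  ramp <- seq(60, 90, length.out = length(tt))
  hr2 <- heart_rate_series(mk_pulse(ramp), fs)
  mid <- seq(10 * fs, length(tt) - 10 * fs)
  expect_true(all(abs(hr2[mid] - ramp[mid]) < 3))
  expect_true(all(diff(hr2[mid]) >= -0.5)) # essentially monotone
  expect_null(heart_rate_series(rep(0.5, length(tt)), fs))
})

test_that("assembled feature sets have 13 series of 268 samples at 2.56 Hz", {
  ss <- small_subject(seed = 5)
  rec <- ss$dataset$recording[[1]]
  pp <- preprocess_trial(rec, 256, ss$dataset$annotations[[1]])
  f <- assemble_features(pp$recording, 256, subject = "S01", trial = 1,
                         quality = "Q1")
  expect_s3_class(f, "feature_set")
  expect_equal(f$fs, 2.56)
  expect_equal(nrow(f$data), 268) # floor(26880 / 100)
  expect_true(all(narx_feature_names() %in% names(f$data)))
  expect_length(narx_feature_names(), 13)
  # determinism of the whole raw-to-features path
  pp2 <- preprocess_trial(rec, 256, ss$dataset$annotations[[1]])
  f2 <- assemble_features(pp2$recording, 256, subject = "S01", trial = 1,
                          quality = "Q1")
  expect_identical(f$data, f2$data)
})

test_that("a flat respiration channel masks the respiration-derived features", {
  ss <- small_subject(seed = 6)
  rec <- ss$dataset$recording[[1]]
  rec$rsp <- 0
  pp <- preprocess_trial(rec, 256)
  f <- assemble_features(pp$recording, 256)
  rsp_feats <- c("rsp_rate", "rsp_rate_deriv", "rsp_running_rate",
                 "inspiration_time", "expiration_time", "inhalation_depth",
                 "exhalation_depth")
  expect_true(all(!f$mask[rsp_feats]))
  expect_true(all(f$mask[setdiff(narx_feature_names(), rsp_feats)]))
  expect_setequal(available_features(f),
                  setdiff(narx_feature_names(), rsp_feats))
  # masked features cannot be requested for modelling
  expect_error(build_regressors(f, lag_spec(1, "rsp_rate", 1, 1)),
               "masked")
})

test_that("breath sample-and-hold series are piecewise constant", {
  ss <- small_subject(seed = 7)
  rec <- ss$dataset$recording[[1]]
  pp <- preprocess_trial(rec, 256)
  cycles <- breath_segmentation(pp$recording$rsp, 256)
  bf <- breath_features(cycles, nrow(pp$recording), 256)
  d <- diff(bf$inspiration_time)
  expect_gt(mean(d == 0), 0.95) # steps only at cycle boundaries
})
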