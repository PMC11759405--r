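test_that("recordings have the expected sample count and ranges", {
  ss <- small_subject(seed = 3)
  rec <- ss$dataset$recording[[1]]
  expect_equal(nrow(rec), 107 * 256) # 27392 samples
  expect_true(all(rec$intensity >= 0 & rec$intensity <= 1))
  expect_equal(ncol(rec), 5)
})

test_that("null-response profile gives flat channels and near-zero intensity off stimulus", {
  prof <- subject_profile(gsr_drift_us_min = 0, scr_gain_us = 0.5,
                          hr_gain_bpm = 0, hr_var_bpm = 0,
                          rsp_rate_gain_bpm = 0, rsp_depth_gain = 0,
                          rsp_var_bpm = 0,
                          noise_gsr = 0, noise_pulse = 0, noise_rsp = 0)
  prof$scr_gain_us <- 0 # fully null SCRs
  ss <- small_subject(seed = 4, profile = prof)
  rec <- ss$dataset$recording[[1]]
  expect_equal(rec$gsr, rep(prof$gsr_baseline_us, nrow(rec)))
  # intensity decays essentially to zero over the 60 s black/neutral tail
  tail_idx <- rec$time_s > 90
  expect_true(all(rec$intensity[tail_idx] < 1e-3))
})

test_that("SCR amplitude is monotone in the nominal image intensity", {
  # noiseless single-image comparison: doubled level, strictly larger peak
  peak_for <- function(level) {
    prof <- subject_profile(gsr_drift_us_min = 0, noise_gsr = 0,
                            noise_pulse = 0, noise_rsp = 0,
                            hr_var_bpm = 0, rsp_var_bpm = 0)
    cfg <- protocol_config(n_subjects = 1, qualities = "Q1",
                           trials_per_quality = 2, image_levels = level)
    tl <- generate_protocol(cfg, seed = 1)
    ds <- generate_recording(tl, prof, cfg, seed = 1)
    max(ds$recording[[1]]$gsr) - prof$gsr_baseline_us
  }
  p1 <- peak_for(0.3)
  p2 <- peak_for(0.6)
  expect_gt(p2, p1)
  expect_equal(p2 / p1, 2, tolerance = 0.05) # peak scales with amplitude
})

test_that("recordings are reproducible from the seed", {
  a <- small_subject(seed = 11)$dataset
  b <- small_subject(seed = 11)$dataset
  expect_identical(a$recording[[2]], b$recording[[2]])
})

test_that("null NARX process produces the zero series", {
  U <- toy_feature_table(50)
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  proc <- true_narx_process(spec, a = 0, b_lin = list(c(0, 0)),
                            noise_sd = 0)
  y <- generate_intensity_from_narx(U, proc, seed = 1)
  expect_true(all(y$y_raw == 0))
  expect_true(all(y$y_scaled == 0)) # degenerate range maps to 0
})

test_that("linear recursion converges to its fixed point", {
  # y(t) = 0.5 y(t-1) + 0.3 u(t-1), u == 1  ->  y* = 0.3 / 0.5 = 0.6
  U <- tibble::tibble(u1 = rep(1, 200), intensity = 0)
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  proc <- true_narx_process(spec, a = 0.5, b_lin = list(c(0.3, 0)),
                            noise_sd = 0)
  y <- generate_intensity_from_narx(U, proc, seed = 1)
  expect_equal(tail(y$y_raw, 1), 0.6, tolerance = 1e-9)
})

test_that("NARX generation is seeded and guards against instability", {
  U <- toy_feature_table(80)
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  proc <- true_narx_process(spec, a = 0.5, b_lin = list(c(0.2, 0.1)),
                            noise_sd = 0.5)
  y1 <- generate_intensity_from_narx(U, proc, seed = 9)
  y2 <- generate_intensity_from_narx(U, proc, seed = 9)
  expect_identical(y1, y2)
  unstable <- true_narx_process(spec, a = 1.5, b_lin = list(c(1, 1)),
                                noise_sd = 0.5)
  expect_error(generate_intensity_from_narx(U, unstable, seed = 1),
               "unstable")
})

test_that("coupled benchmark subjects carry the generated intensity", {
  trials <- simulate_coupled_subject(2, subject = "SX")
  expect_length(trials, 7)
  expect_s3_class(trials[[1]], "feature_set")
  expect_true(all(vapply(trials, function(f) {
    all(f$data$intensity >= 0 & f$data$intensity <= 1)
  }, logical(1))))
})
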