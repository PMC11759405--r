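test_that("lag specs enforce the integer search bounds", {
  expect_error(lag_spec(12, "u1", 1, 1), "\\[1, 11\\]")
  expect_error(lag_spec(2, "u1", 0, 1), "\\[1, 11\\]")
  expect_error(lag_spec(2, c("a", "b", "c", "d"), rep(1, 4), rep(1, 4)),
               "1 to 3")
  sp <- lag_spec(2, "u1", 3, 4)
  expect_equal(narxaffect:::max_lookback(sp), 7)
})

test_that("regressor layout matches the written-out lag structure", {
  # n_y = 1, one feature with n_u = 1, n_k = 1, T = 10:
  # 8 rows; columns y(t-1), u(t-1), u(t-2), u(t-1)^2, u(t-2)^2
  tab <- toy_feature_table(10, features = "u1")
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  br <- build_regressors(tab, spec)
  expect_equal(nrow(br$Z), 8)
  expect_equal(colnames(br$Z),
               c("y_lag1", "u1_lag1", "u1_lag2", "u1_lag1_sq", "u1_lag2_sq"))
  expect_equal(br$Z[, "u1_lag1"]^2, br$Z[, "u1_lag1_sq"])
  expect_equal(br$y, tab$intensity[3:10])
  # all-zero feature: quadratic columns all zero
  tab$u1 <- 0
  brz <- build_regressors(tab, spec)
  expect_true(all(brz$Z[, c("u1_lag1_sq", "u1_lag2_sq")] == 0))
})

test_that("regressor construction matches the naive loop oracle", {
  feats <- paste0("u", 1:3)
  withr::with_seed(99, {
    for (rep in 1:10) {
      m <- sample(1:3, 1)
      spec <- lag_spec(sample(1:4, 1), feats[seq_len(m)],
                       n_u = sample(1:4, m, replace = TRUE),
                       n_k = sample(1:4, m, replace = TRUE))
      tab <- toy_feature_table(40, seed = rep, features = feats)
      br <- build_regressors(tab, spec)
      oracle <- naive_regressors(tab$intensity,
                                 as.matrix(tab[, spec$features]), spec)
      expect_equal(unname(br$Z), unname(oracle))
    }
  })
})

test_that("a noiseless linear process is fitted exactly", {
  tab <- toy_feature_table(120, features = "u1")
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  proc <- true_narx_process(spec, a = 0.5, b_lin = list(c(0.3, 0.1)),
                            noise_sd = 0)
  tab$intensity <- generate_intensity_from_narx(tab, proc, seed = 1)$y_raw
  fs <- feature_set(tab, fs = 2.56)
  model <- fit_narx(fs, spec, control = narx_control(n_units = 0))
  expect_lt(model$resid_var, 1e-6)
  # in the linear special case the wavelet stage adds (almost) nothing
  model_w <- fit_narx(fs, spec, control = narx_control(n_units = 8))
  amps <- vapply(model_w$units, `[[`, numeric(1), "amplitude")
  expect_lt(sum(abs(amps)), 1e-3)
})

test_that("constant targets collapse to the offset", {
  tab <- toy_feature_table(60, features = "u1")
  tab$intensity <- 0.4
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  model <- fit_narx(feature_set(tab, 2.56), spec,
                    control = narx_control(n_units = 0))
  expect_equal(model$y0, 0.4)
  sim <- simulate_narx(model, feature_set(tab, 2.56))
  expect_equal(sim$y_hat, rep(0.4, nrow(sim)), tolerance = 1e-8)
})

test_that("quadratic regressors capture a quadratic map better than linear only", {
  tab <- toy_feature_table(150, features = "u1")
  tab$intensity <- c(0, tab$u1[-nrow(tab)]^2) # y(t) = u(t-1)^2
  fs <- feature_set(tab, 2.56)
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 1)
  full <- fit_narx(fs, spec, control = narx_control(n_units = 0))
  # ablation: drop the squared columns before solving
  br <- build_regressors(fs, spec)
  lin_cols <- !grepl("_sq$", colnames(br$Z))
  A <- cbind(1, br$Z[, lin_cols])
  beta <- qr.solve(A, br$y)
  mse_lin <- mean((br$y - A %*% beta)^2)
  expect_lt(full$resid_var, mse_lin / 10)
})

test_that("free-run simulation recovers a held-out trial of the generator", {
  trials <- lapply(1:3, function(i) {
    tab <- toy_feature_table(120, seed = i, features = "u1")
    spec <- lag_spec(2, "u1", n_u = 2, n_k = 1)
    proc <- true_narx_process(spec, a = c(0.5, 0.2),
                              b_lin = list(c(0.3, 0.2, 0.1)), noise_sd = 0)
    tab$intensity <- generate_intensity_from_narx(tab, proc, seed = i)$y_raw
    feature_set(tab, 2.56)
  })
  spec <- lag_spec(2, "u1", n_u = 2, n_k = 1)
  model <- fit_narx(trials[1:2], spec, control = narx_control(n_units = 0))
  sim <- simulate_narx(model, trials[[3]])
  expect_gte(pearson_r(sim$y_hat, sim$y_true), 0.99)
  expect_equal(attr(sim, "mode"), "free_run")
})

test_that("one-step mode reproduces the stored training residual variance", {
  tab <- toy_feature_table(100, features = "u1")
  spec <- lag_spec(1, "u1", n_u = 1, n_k = 2)
  fs <- feature_set(tab, 2.56)
  model <- fit_narx(fs, spec, control = narx_control(n_units = 0))
  sim <- simulate_narx(model, fs, mode = "one_step")
  expect_equal(stats::var(sim$y_true - sim$y_hat), model$resid_var,
               tolerance = 1e-8)
  expect_equal(attr(sim, "mode"), "one_step")
})

test_that("models survive a serialisation round trip bit-identically", {
  trials <- simulate_coupled_subject(3)
  spec <- narx_ground_truth_process()$spec
  model <- fit_narx(trials[1:2], spec, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  model2 <- readRDS(path)
  s1 <- simulate_narx(model, trials[[3]])
  s2 <- simulate_narx(model2, trials[[3]])
  expect_identical(s1$y_hat, s2$y_hat)
})

test_that("pearson_r follows the documented conventions", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, rep(1, 20)), 0) # zero-variance convention
  expect_error(pearson_r(x, x[-1]), "mismatch")
})
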