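#' Integer lag structure of a NARX model
#'
#' The model output (intensity) enters with `n_y` linear lags; each selected
#' physiological feature `m` enters with `n_u[m] + 1` linear terms at lags
#' `n_k[m] ... n_k[m] + n_u[m]` together with the squares of those same
#' terms.  All parameters are integers searched over `[1, 11]` (at 2.56 Hz,
#' 0.39 s to 4.29 s); at most 3 features are combined.
#'
#' @param n_y Output lag count.
#' @param features Character vector of feature names (length 1--3).
#' @param n_u Input lag counts, one per feature.
#' @param n_k Input delays, one per feature.
#' @param bounds Inclusive integer bounds every parameter must respect.
#' @return An object of class `lag_spec`.
#' @export
#' @examples
#' lag_spec(2, "hr_filtered", n_u = 3, n_k = 1)
lag_spec <- function(n_y, features, n_u, n_k, bounds = c(1L, 11L)) {
  m <- length(features)
  if (m < 1 || m > 3) abort("1 to 3 features required")
  stopifnot(length(n_u) == m, length(n_k) == m)
  par <- c(n_y, n_u, n_k)
  if (any(par != round(par))) abort("lag parameters must be integers")
  if (any(par < bounds[1] | par > bounds[2])) {
    abort(sprintf("lag parameters must lie in [%d, %d]", bounds[1], bounds[2]))
  }
  structure(
    list(n_y = as.integer(n_y), features = as.character(features),
         n_u = as.integer(n_u), n_k = as.integer(n_k),
         bounds = as.integer(bounds)),
    class = "lag_spec"
  )
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("<lag_spec> n_y=%d | %s\n", x$n_y,
              paste(sprintf("%s(n_u=%d, n_k=%d)", x$features, x$n_u, x$n_k),
                    collapse = ", ")))
  invisible(x)
}

# parameter vector (n_y, nu1, nk1, ..., num, nkm) <-> lag_spec
lag_spec_from_par <- function(par, features, bounds = c(1L, 11L)) {
  m <- length(features)
  stopifnot(length(par) == 1 + 2 * m)
  lag_spec(par[1], features, n_u = par[1 + seq_len(m)],
           n_k = par[1 + m + seq_len(m)], bounds = bounds)
}

lag_spec_par <- function(spec) c(spec$n_y, spec$n_u, spec$n_k)

max_lookback <- function(spec) max(spec$n_y, max(spec$n_k + spec$n_u))

#' Build the NARX regressor matrix and target
#'
#' Transcribes the model's regressor vector literally: for each valid time
#' index `t` the row holds `y(t-1) ... y(t-n_y)`, then for each feature the
#' linear terms `u(t-n_k) ... u(t-n_k-n_u)` followed by their squares.  The
#' target is `y(t)`.
#'
#' @param features A [feature_set()] (whose `intensity` column is the
#'   output), or a plain tibble/data frame with an `intensity` column plus
#'   the feature columns named in `spec`.
#' @param spec A [lag_spec()].  Requesting a masked feature is an error.
#' @param y Optional explicit output series overriding the `intensity`
#'   column.
#' @return A list with `Z` (matrix, named columns), `y` (targets) and `t`
#'   (the time indices of the rows in the original series).
#' @export
build_regressors <- function(features, spec, y = NULL) {
  stopifnot(inherits(spec, "lag_spec"))
  U <- feature_matrix(features, spec$features)
  if (is.null(y)) {
    data <- if (inherits(features, "feature_set")) features$data else
      tibble::as_tibble(features)
    if (!"intensity" %in% names(data)) abort("no intensity column found")
    y <- data$intensity
  }
  n <- length(y)
  stopifnot(nrow(U) == n)
  maxlook <- max_lookback(spec)
  if (n <= maxlook + 1) abort("series too short for the requested lags")
  if (any(!is.finite(y)) || any(!is.finite(U))) {
    abort("non-finite values in output or features")
  }
  t_idx <- (maxlook + 1):n
  cols <- list()
  for (i in seq_len(spec$n_y)) {
    cols[[paste0("y_lag", i)]] <- y[t_idx - i]
  }
  for (j in seq_along(spec$features)) {
    f <- spec$features[j]
    lags <- spec$n_k[j] + 0:spec$n_u[j]
    lin <- lapply(lags, function(l) U[t_idx - l, j])
    names(lin) <- paste0(f, "_lag", lags)
    sq <- lapply(lin, function(v) v^2)
    names(sq) <- paste0(f, "_lag", lags, "_sq")
    cols <- c(cols, lin, sq)
  }
  Z <- do.call(cbind, cols)
  list(Z = Z, y = y[t_idx], t = t_idx)
}

#' Fitting controls for NARX models
#'
#' @param n_units Maximum number of wavelet/scaling units (0 disables the
#'   nonlinear part, reducing the model to the linear-plus-quadratic
#'   regression on the same regressors).
#' @param n_candidates Training samples subsampled as candidate unit
#'   centres.
#' @param dilations Dyadic dilation factors tried for every centre.
#' @param tol_improve Minimum relative residual-variance improvement for
#'   accepting another unit.
#' @param pca_var Variance fraction the principal-axes projection retains.
#' @param divergence_bound Free-run simulation aborts beyond this magnitude.
#' @return A list of class `narx_control`.
#' @export
narx_control <- function(n_units = 8, n_candidates = 50,
                         dilations = 2^(0:3), tol_improve = 1e-4,
                         pca_var = 1 - 1e-6, divergence_bound = 1e3) {
  structure(as.list(environment()), class = "narx_control")
}

#' Fit a NARX wavelet-network model
#'
#' Regressors are pooled over the training trials (never across a trial
#' boundary), standardised, and projected onto their principal axes keeping
#' essentially all variance.  The linear part is an offset (the pooled
#' target mean) plus least-squares weights on the projected regressors; the
#' nonlinear part adds radial wavelet units (Mexican hat,
#' `(d - rho) exp(-rho/2)`) and Gaussian scaling units (`exp(-rho/2)`)
#' greedily on the linear fit's residual, with candidate centres drawn from
#' the training samples at dyadic dilations, until the configured unit count
#' or until the residual variance stops improving.
#'
#' @param trials A [feature_set()], or a list of them (one per training
#'   trial).
#' @param spec A [lag_spec()].
#' @param control A [narx_control()].
#' @param seed Seed for the candidate-centre subsample.
#' @return An object of class `narx_model`.
#' @export
fit_narx <- function(trials, spec, control = narx_control(), seed = 1L) {
  if (inherits(trials, "feature_set")) trials <- list(trials)
  built <- lapply(trials, build_regressors, spec = spec)
  fit_narx_built(built, spec, control, seed)
}

# fit from prebuilt regressor blocks (one per trial); the principal axes
# come from the eigendecomposition of the regressor correlation matrix,
# which is the same projection as an SVD of the standardised regressors
fit_narx_built <- function(built, spec, control, seed = 1L) {
  Z <- do.call(rbind, lapply(built, `[[`, "Z"))
  y <- unlist(lapply(built, `[[`, "y"))

  mu <- colMeans(Z)
  sigma <- sqrt(colMeans(Z^2) - mu^2) * sqrt(nrow(Z) / (nrow(Z) - 1))
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, mu), 2, sigma, "/")

  eg <- eigen(crossprod(Zs), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  keep <- if (tot > 0) which(cumsum(ev) / tot >= control$pca_var)[1] else 1L
  idx <- seq_len(keep)
  idx <- idx[ev[idx] > 1e-10 * max(ev)] # guard against null directions
  P <- eg$vectors[, idx, drop = FALSE]
  X <- Zs %*% P

  y0 <- mean(y)
  # X has orthogonal columns with crossprod(X) = diag(ev[idx])
  l <- drop(crossprod(X, y - y0)) / ev[idx]
  resid <- y - y0 - drop(X %*% l)

  units <- list()
  if (control$n_units > 0 && nrow(X) > 2) {
    units <- fit_wavelet_units(X, resid, control, seed)
    for (u in units) resid <- resid - u$amplitude * unit_output(X, u)
  }

  structure(
    list(spec = spec, y0 = y0, mu = mu, sigma = sigma, P = P, l = l,
         units = units, resid_var = stats::var(resid),
         n_train = length(y), control = control, seed = seed,
         colnames = colnames(Z)),
    class = "narx_model"
  )
}

# radial unit response on projected regressors
unit_output <- function(X, unit) {
  D <- sweep(X, 2, unit$center)
  rho <- rowSums(D^2) * unit$dilation^2
  if (unit$type == "wavelet") (ncol(X) - rho) * exp(-rho / 2) else
    exp(-rho / 2)
}

# greedy selection of wavelet/scaling units on the residual
fit_wavelet_units <- function(X, resid, control, seed) {
  n <- nrow(X)
  idx <- with_seed(seed, sample.int(n, min(control$n_candidates, n)))
  cand <- list()
  for (i in idx) {
    for (a in control$dilations) {
      for (type in c("wavelet", "scaling")) {
        cand[[length(cand) + 1]] <-
          list(center = X[i, ], dilation = a, type = type)
      }
    }
  }
  outs <- vapply(cand, function(u) unit_output(X, u), numeric(n))
  units <- list()
  for (step in seq_len(control$n_units)) {
    ss_before <- sum(resid^2)
    if (ss_before <= 0) break
    num <- drop(crossprod(outs, resid))
    den <- colSums(outs^2)
    gain <- ifelse(den > 1e-12, num^2 / den, 0)
    best <- which.max(gain)
    if (gain[best] / ss_before <= control$tol_improve) break
    amp <- num[best] / den[best]
    u <- cand[[best]]
    u$amplitude <- amp
    units[[length(units) + 1]] <- u
    resid <- resid - amp * outs[, best]
  }
  units
}

# prediction from raw regressor rows
predict_narx_z <- function(model, Z) {
  Zs <- sweep(sweep(Z, 2, model$mu), 2, model$sigma, "/")
  X <- Zs %*% model$P
  pred <- model$y0 + drop(X %*% model$l)
  for (u in model$units) pred <- pred + u$amplitude * unit_output(X, u)
  pred
}

#' Simulate a fitted NARX model on a trial
#'
#' In `free_run` mode (the default, and the stronger claim) the first
#' `max`-lag output values are taken from the trial's ground truth and every
#' subsequent output lag comes from the model's own predictions, while the
#' exogenous lags always come from the trial's features.  `one_step` mode
#' takes every output lag from the ground truth instead.
#'
#' @param model A fitted [fit_narx()] model.
#' @param features A [feature_set()] for the test trial (its `intensity` is
#'   the ground truth).
#' @param y_init Optional replacement for the initial ground-truth samples
#'   (length `>= max` lookback).
#' @param mode `"free_run"` or `"one_step"`.
#' @return A tibble with `t` (time index in the trial), `y_hat` and
#'   `y_true`; attribute `mode` records the simulation mode.
#' @export
simulate_narx <- function(model, features,
                          y_init = NULL, mode = c("free_run", "one_step")) {
  mode <- match.arg(mode)
  spec <- model$spec
  U <- feature_matrix(features, spec$features)
  data <- if (inherits(features, "feature_set")) features$data else
    tibble::as_tibble(features)
  y_true <- data$intensity
  n <- length(y_true)
  maxlook <- max_lookback(spec)
  if (n <= maxlook + 1) abort("test trial too short for the model's lags")
  bound <- model$control$divergence_bound

  if (mode == "one_step") {
    br <- build_regressors(features, spec)
    pred <- predict_narx_z(model, br$Z)
    out <- tibble::tibble(t = br$t, y_hat = pred, y_true = y_true[br$t])
    attr(out, "mode") <- mode
    return(out)
  }

  ybuf <- y_true
  if (!is.null(y_init)) {
    stopifnot(length(y_init) >= maxlook)
    ybuf[seq_len(maxlook)] <- y_init[seq_len(maxlook)]
  }
  # precompute the standardised linear weights for speed
  w_lin <- drop(model$P %*% model$l)
  t_idx <- (maxlook + 1):n
  m <- length(spec$features)
  p <- length(model$mu)
  z <- numeric(p)
  for (t in t_idx) {
    pos <- 0L
    for (i in seq_len(spec$n_y)) z[pos + i] <- ybuf[t - i]
    pos <- spec$n_y
    for (j in seq_len(m)) {
      lags <- spec$n_k[j] + 0:spec$n_u[j]
      u <- U[t - lags, j]
      k <- length(u)
      z[pos + seq_len(k)] <- u
      z[pos + k + seq_len(k)] <- u^2
      pos <- pos + 2L * k
    }
    zs <- (z - model$mu) / model$sigma
    pred <- model$y0 + sum(zs * w_lin)
    if (length(model$units)) {
      x <- drop(crossprod(model$P, zs))
      for (uu in model$units) {
        rho <- sum((x - uu$center)^2) * uu$dilation^2
        pred <- pred + uu$amplitude *
          (if (uu$type == "wavelet") (length(x) - rho) * exp(-rho / 2) else
             exp(-rho / 2))
      }
    }
    if (!is.finite(pred) || abs(pred) > bound) {
      abort(sprintf("free-run simulation diverged at t=%d", t))
    }
    ybuf[t] <- pred
  }
  out <- tibble::tibble(t = t_idx, y_hat = ybuf[t_idx], y_true = y_true[t_idx])
  attr(out, "mode") <- mode
  out
}

#' Pearson correlation with a documented degenerate-case convention
#'
#' Standard product-moment correlation; if either series has zero variance
#' the correlation is undefined and this function returns 0 (so a constant
#' prediction scores as uninformative rather than propagating `NA`).
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @return A number in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch")
  if (length(a) < 2) abort("need at least 2 samples")
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}
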