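#' Sliding-window statistics table for the linear-regression baseline
#'
#' Windows of 13 samples (about 5 s at 2.56 Hz) advancing by 3 samples
#' (about 1 s); per window and selected feature the maximum, minimum, mean
#' and population standard deviation are the predictors, and the mean
#' intensity over the window is the target.  The baseline therefore never
#' sees per-sample intensity, only window means.  The incomplete trailing
#' window is dropped.
#'
#' @param features A [feature_set()] or plain tibble with `intensity`.
#' @param selected Character vector of feature names to include.
#' @param window,step Window length and step in samples.
#' @return A tibble of windows (`window`, `start`, predictors named
#'   `<feature>_max/min/mean/std`, `target`); attribute `registry` stores
#'   the predictor column names.
#' @export
#' @examples
#' # floor((103 - 13) / 3) + 1 = 31 windows for a 103-sample trial
windowize <- function(features, selected, window = 13L, step = 3L) {
  U <- feature_matrix(features, selected)
  data <- if (inherits(features, "feature_set")) features$data else
    tibble::as_tibble(features)
  y <- data$intensity
  n <- length(y)
  if (n < window) abort("trial shorter than one window")
  starts <- seq(1L, n - window + 1L, by = step)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rows <- lapply(seq_along(starts), function(w) {
    idx <- starts[w] + 0:(window - 1L)
    vals <- lapply(selected, function(f) {
      v <- U[idx, f]
      stats::setNames(
        list(max(v), min(v), mean(v), pop_sd(v)),
        paste0(f, c("_max", "_min", "_mean", "_std"))
      )
    })
    tibble::as_tibble(c(list(window = w, start = starts[w]),
                        unlist(vals, recursive = FALSE),
                        list(target = mean(y[idx]))))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "registry") <- setdiff(names(out), c("window", "start", "target"))
  out
}

#' Fit the sliding-window linear regression
#'
#' Ordinary least squares of the window-mean intensity on the window
#' statistics, with an intercept; rank deficiency falls back to the
#' minimum-norm solution.
#'
#' @param tables One window table from [windowize()] or a list of them
#'   (pooled over training trials).
#' @return A list of class `window_lr` with `intercept`, `coef` (named) and
#'   the column `registry`.
#' @export
fit_window_lr <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  registry <- attr(tables[[1]], "registry")
  for (tb in tables) {
    if (!identical(attr(tb, "registry"), registry)) {
      abort("window tables have mismatched column registries")
    }
  }
  pooled <- dplyr::bind_rows(tables)
  X <- as.matrix(pooled[, registry, drop = FALSE])
  y <- pooled$target
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    abort("non-finite values in window table")
  }
  A <- cbind(`(Intercept)` = 1, X)
  beta <- lstsq_minnorm(A, y)
  structure(
    list(intercept = beta[1],
         coef = stats::setNames(beta[-1], registry),
         registry = registry),
    class = "window_lr"
  )
}

#' Predict from a sliding-window linear regression
#'
#' @param model A [fit_window_lr()] model.
#' @param table A window table with the same column registry.
#' @return A list with `predictions` (tibble of `window`, `y_hat`,
#'   `target`) and `r`, the Pearson correlation between predicted and
#'   target window means (zero-variance convention as in [pearson_r()]).
#' @export
predict_window_lr <- function(model, table) {
  if (!identical(attr(table, "registry"), model$registry)) {
    abort("window table does not match the model's column registry")
  }
  X <- as.matrix(table[, model$registry, drop = FALSE])
  y_hat <- model$intercept + drop(X %*% model$coef)
  list(
    predictions = tibble::tibble(window = table$window, y_hat = y_hat,
                                 target = table$target),
    r = pearson_r(y_hat, table$target)
  )
}
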