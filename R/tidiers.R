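#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted NARX model
#'
#' One row per model term: the linear weights expressed in the projected
#' coordinate system, followed by the wavelet/scaling unit amplitudes.
#'
#' @param x A [fit_narx()] model.
#' @param ... Unused.
#' @return A tibble with `term`, `type`, `estimate`.
#' @method tidy narx_model
#' @export
tidy.narx_model <- function(x, ...) {
  lin <- tibble::tibble(
    term = c("(offset)", paste0("pc", seq_along(x$l))),
    type = c("offset", rep("linear", length(x$l))),
    estimate = c(x$y0, x$l)
  )
  if (length(x$units)) {
    un <- tibble::tibble(
      term = paste0("unit", seq_along(x$units)),
      type = vapply(x$units, `[[`, character(1), "type"),
      estimate = vapply(x$units, `[[`, numeric(1), "amplitude")
    )
    lin <- dplyr::bind_rows(lin, un)
  }
  lin
}

#' Glance at a fitted NARX model
#'
#' @param x A [fit_narx()] model.
#' @param ... Unused.
#' @return A one-row tibble: regressor/projection dimensions, unit count,
#'   training rows and residual variance.
#' @method glance narx_model
#' @export
glance.narx_model <- function(x, ...) {
  tibble::tibble(
    n_y = x$spec$n_y, m = length(x$spec$features),
    n_regressors = length(x$mu), n_components = ncol(x$P),
    n_units = length(x$units), n_train = x$n_train,
    resid_var = x$resid_var
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [loocv_evaluate()].
#' @param ... Unused.
#' @return One row per fold: `subject`, `quality`, `model_kind`, `fold`,
#'   `r`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(subject = x$subject, quality = x$quality,
                 model_kind = x$model_kind,
                 fold = seq_along(x$fold_r), r = x$fold_r)
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(subject = x$subject, quality = x$quality,
                 model_kind = x$model_kind,
                 features = paste(x$features, collapse = "+"),
                 n_features = length(x$features), mean_r = x$mean_r)
}

#' Plot a trial's feature set
#'
#' Facets the available feature series (and the intensity trace) over the
#' trial's time base — the quickest way to inspect what the model actually
#' sees at 2.56 Hz.
#'
#' @param object A [feature_set()].
#' @param features Which features to show (defaults to all available).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_set
#' @export
autoplot.feature_set <- function(object, features = NULL, ...) {
  features <- features %||% available_features(object)
  long <- tidyr::pivot_longer(
    object$data[, c("time_s", features, "intensity")],
    -dplyr::all_of("time_s"),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(long$series, levels = c(features, "intensity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s %s trial %s", object$subject,
                                  object$quality, object$trial)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot predicted against reported intensity
#'
#' @param simulation Output of [simulate_narx()].
#' @param fs Sampling rate used to convert the time index to seconds.
#' @return A ggplot object.
#' @export
plot_prediction <- function(simulation, fs = 2.56) {
  long <- tidyr::pivot_longer(simulation, c("y_hat", "y_true"),
                              names_to = "series", values_to = "intensity")
  long$series <- c(y_hat = "predicted", y_true = "reported")[long$series]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t / fs, y = .data$intensity,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "emotion intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a feature-occurrence ranking
#'
#' Histogram-style bar chart of how many subjects carry each feature in
#' their optimal set, per quality and model kind.
#'
#' @param ranking Output of [rank_features()].
#' @return A ggplot object.
#' @export
plot_feature_ranking <- function(ranking) {
  ranking$feature <- factor(ranking$feature, levels = rev(narx_feature_names()))
  ggplot2::ggplot(ranking, ggplot2::aes(x = .data$count, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$quality ~ .data$model_kind) +
    ggplot2::labs(x = "subjects with the feature in their optimal set",
                  y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
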