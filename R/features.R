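#' @name feature_set
#' @title Time-aligned feature matrix for one trial
#'
#' @description A `feature_set` bundles the 13 feature series of one trial,
#' decimated to the analysis rate (2.56 Hz by default), with the intensity
#' trace on the same time base and a per-feature availability mask.  Masked
#' features (for example breath timing on an unusable respiration channel)
#' carry `NA` and are excluded from a subject's candidate set during feature
#' selection; they are never silently imputed.
#'
#' @param data Tibble with `time_s`, the 13 feature columns and `intensity`.
#' @param fs Sampling rate of the series in Hz.
#' @param mask Named logical vector over [narx_feature_names()]; `TRUE`
#'   means available.
#' @param subject,trial,quality Trial metadata.
#' @return An object of class `feature_set`.
NULL

#' @rdname feature_set
#' @export
feature_set <- function(data, fs, mask = NULL, subject = NA_character_,
                        trial = NA_integer_, quality = NA_character_) {
  feats <- narx_feature_names()
  stopifnot(all(c("intensity", intersect(feats, names(data))) %in% names(data)))
  mask <- mask %||% stats::setNames(feats %in% names(data), feats)
  stopifnot(setequal(names(mask), feats))
  structure(
    list(data = tibble::as_tibble(data), fs = fs, mask = mask[feats],
         subject = subject, trial = trial, quality = quality),
    class = "feature_set"
  )
}

#' @rdname feature_set
#' @param x A `feature_set`.
#' @param ... Unused.
#' @method as_tibble feature_set
#' @export
as_tibble.feature_set <- function(x, ...) x$data

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> subject %s trial %s quality %s | %d samples @ %.3g Hz | %d/13 features available\n",
    x$subject, x$trial, x$quality, nrow(x$data), x$fs, sum(x$mask)
  ))
  invisible(x)
}

#' @rdname feature_set
#' @export
available_features <- function(x) names(which(x$mask))

# matrix of named feature columns; errors on masked/missing requests
feature_matrix <- function(features, names) {
  data <- if (inherits(features, "feature_set")) {
    # the availability mask governs the 13 canonical features; other
    # columns (e.g. toy inputs in examples) only need to be present
    canon <- intersect(names, narx_feature_names())
    miss <- setdiff(canon, available_features(features))
    if (length(miss)) {
      abort(paste0("requested masked/unavailable feature(s): ",
                   paste(miss, collapse = ", ")))
    }
    features$data
  } else {
    tibble::as_tibble(features)
  }
  if (!all(names %in% colnames(data))) {
    abort("requested feature column(s) not present")
  }
  as.matrix(data[, names, drop = FALSE])
}

# local maxima with prominence and minimum-distance constraints;
# `window` bounds the prominence search on each side (samples)
find_peaks <- function(x, min_prominence = 0, min_distance = 1,
                       window = Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  # refractory distance first (keeping the taller extremum), so that the
  # prominence pass only touches one candidate per refractory period
  if (min_distance > 1 && length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    sel <- logical(n)
    kept <- integer(0)
    for (i in ord) {
      if (!any(sel[max(1, i - min_distance):min(n, i + min_distance)])) {
        sel[i] <- TRUE
        kept <- c(kept, i)
      }
    }
    cand <- sort(kept)
  }
  prom <- vapply(cand, function(i) {
    lo <- max(1, i - window)
    hi <- min(n, i + window)
    left <- x[seq(lo, i - 1)]
    right <- x[seq(i + 1, hi)]
    hb <- which(left > x[i])
    lo_l <- min(left[seq(if (length(hb)) max(hb) else 1, length(left))])
    hb <- which(right > x[i])
    lo_r <- min(right[seq_len(if (length(hb)) min(hb) else length(right))])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  sort(cand[prom >= min_prominence])
}

#' Instantaneous heart-rate series from the pulse channel
#'
#' Detects systolic peaks (prominence threshold at 0.3 of the signal's
#' inter-quartile range, 0.3 s refractory period), converts inter-beat
#' intervals to beats per minute, rejects beats outside 30--200 bpm, and
#' linearly interpolates the remaining beat-to-beat rates onto the uniform
#' pulse time base.
#'
#' @param pulse Filtered pulse series.
#' @param fs Sampling rate in Hz.
#' @return Numeric HR series (bpm) of the same length, or `NULL` when fewer
#'   than 3 usable beats were found (the feature is then masked upstream).
#' @export
heart_rate_series <- function(pulse, fs) {
  iqr <- stats::IQR(pulse)
  if (!is.finite(iqr) || iqr <= 0) return(NULL)
  pk <- find_peaks(pulse, min_prominence = 0.3 * iqr,
                   min_distance = round(0.3 * fs), window = round(10 * fs))
  if (length(pk) < 3) return(NULL)
  ibi <- diff(pk) / fs
  bpm <- 60 / ibi
  mid <- (pk[-1] + pk[-length(pk)]) / 2
  ok <- bpm >= 30 & bpm <= 200
  # artifact rejection: drop beats deviating > 30% from the local median IBI
  if (sum(ok) >= 5) {
    med <- stats::runmed(ibi, k = min(9L, 2 * (sum(ok) %/% 2) - 1))
    ok <- ok & abs(ibi - med) <= 0.3 * med
  }
  if (sum(ok) < 2) return(NULL)
  stats::approx(mid[ok], bpm[ok], xout = seq_along(pulse), rule = 2)$y
}

#' Segment the respiration signal into breath cycles
#'
#' Alternating trough/peak/next-trough triplets from prominence-thresholded
#' extrema (0.3 of the inter-quartile range) with a minimum extremum spacing
#' of 1.5 s.  Runs of same-type extrema are collapsed to the most extreme
#' one so the sequence alternates strictly.
#'
#' @param rsp Band-passed respiration series.
#' @param fs Sampling rate in Hz.
#' @param min_prominence Absolute prominence threshold in signal units;
#'   the default adapts to the trial (0.3 of the inter-quartile range).
#' @return A tibble of cycles (`t_trough`, `t_peak`, `t_next_trough` in
#'   seconds, `inspiration_time`, `expiration_time`, `inhalation_depth`,
#'   `exhalation_depth`, `rate_bpm`), possibly empty.
#' @export
breath_segmentation <- function(rsp, fs, min_prominence = NULL) {
  empty <- tibble::tibble(
    t_trough = numeric(0), t_peak = numeric(0), t_next_trough = numeric(0),
    inspiration_time = numeric(0), expiration_time = numeric(0),
    inhalation_depth = numeric(0), exhalation_depth = numeric(0),
    rate_bpm = numeric(0)
  )
  iqr <- stats::IQR(rsp)
  if (!is.finite(iqr) || iqr <= 0) return(empty)
  thr <- min_prominence %||% (0.3 * iqr)
  dist <- round(1.5 * fs / 2)
  win <- round(30 * fs)
  pk <- find_peaks(rsp, thr, dist, window = win)
  tr <- find_peaks(-rsp, thr, dist, window = win)
  if (!length(pk) || !length(tr)) return(empty)
  ext <- rbind(data.frame(i = pk, type = "peak"),
               data.frame(i = tr, type = "trough"))
  ext <- ext[order(ext$i), ]
  # collapse same-type runs, keeping the most extreme sample
  keep <- logical(nrow(ext))
  j <- 1
  while (j <= nrow(ext)) {
    k <- j
    while (k < nrow(ext) && ext$type[k + 1] == ext$type[j]) k <- k + 1
    run <- j:k
    best <- if (ext$type[j] == "peak") run[which.max(rsp[ext$i[run]])] else
      run[which.min(rsp[ext$i[run]])]
    keep[best] <- TRUE
    j <- k + 1
  }
  ext <- ext[keep, ]
  rows <- list()
  for (j in seq_len(nrow(ext) - 2)) {
    if (ext$type[j] == "trough" && ext$type[j + 1] == "peak" &&
        ext$type[j + 2] == "trough") {
      i1 <- ext$i[j]; i2 <- ext$i[j + 1]; i3 <- ext$i[j + 2]
      period <- (i3 - i1) / fs
      if (period < 1.5) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        t_trough = (i1 - 1) / fs, t_peak = (i2 - 1) / fs,
        t_next_trough = (i3 - 1) / fs,
        inspiration_time = (i2 - i1) / fs,
        expiration_time = (i3 - i2) / fs,
        inhalation_depth = rsp[i2] - rsp[i1],
        exhalation_depth = rsp[i2] - rsp[i3],
        rate_bpm = 60 / period
      )
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}

#' Expand breath cycles into uniform-rate series
#'
#' Sample-and-hold: each cycle's values take effect at the cycle's end and
#' hold until the next cycle's end.  Samples before the first cycle end are
#' filled with the first cycle's values so that regressor construction never
#' meets `NA` on an available feature.
#'
#' @param cycles Tibble from [breath_segmentation()].
#' @param n Number of output samples.
#' @param fs Sampling rate of the output time base in Hz.
#' @return A tibble with columns `rsp_rate`, `inspiration_time`,
#'   `expiration_time`, `inhalation_depth`, `exhalation_depth` (all `NA`
#'   when `cycles` is empty).
#' @export
breath_features <- function(cycles, n, fs) {
  cols <- c("rsp_rate", "inspiration_time", "expiration_time",
            "inhalation_depth", "exhalation_depth")
  if (nrow(cycles) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(rep(NA_real_, n)), length(cols)), cols))
    return(out)
  }
  t_out <- (seq_len(n) - 1) / fs
  idx <- findInterval(t_out, cycles$t_next_trough) + 1
  idx <- pmin(pmax(idx, 1), nrow(cycles))
  tibble::tibble(
    rsp_rate = cycles$rate_bpm[idx],
    inspiration_time = cycles$inspiration_time[idx],
    expiration_time = cycles$expiration_time[idx],
    inhalation_depth = cycles$inhalation_depth[idx],
    exhalation_depth = cycles$exhalation_depth[idx]
  )
}

#' Central-difference derivative
#'
#' Central differences scaled to units per second; one-sided differences at
#' the endpoints.
#'
#' @param x Numeric series of length at least 3.
#' @param fs Sampling rate in Hz.
#' @return Numeric series of the same length.
#' @export
derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3) abort("derivative needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Running rate of a series
#'
#' Relative change of the current level with respect to a trailing
#' reference interval that moves along with the evaluation window: at each
#' sample the mean over an evaluation window ending now is compared with the
#' mean over a reference window ending `ref_gap_s` earlier, normalised by
#' the reference magnitude.  The warm-up region (before both windows fit)
#' is zero.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param eval_window_s,ref_window_s,ref_gap_s Window lengths and gap in
#'   seconds (defaults 5, 10, 5).
#' @param eps Stabiliser added to the reference magnitude.
#' @return Numeric series of the same length.
#' @export
running_rate <- function(x, fs, eval_window_s = 5, ref_window_s = 10,
                         ref_gap_s = 5, eps = 1e-6) {
  n <- length(x)
  we <- max(1L, round(eval_window_s * fs))
  wr <- max(1L, round(ref_window_s * fs))
  gap <- round(ref_gap_s * fs)
  need <- we + gap + wr
  if (n <= need) return(numeric(n))
  cs <- c(0, cumsum(x))
  mean_win <- function(end, w) (cs[end + 1] - cs[end + 1 - w]) / w
  out <- numeric(n)
  t_idx <- (need + 1):n
  m_eval <- mean_win(t_idx, we)
  m_ref <- mean_win(t_idx - gap, wr)
  out[t_idx] <- (m_eval - m_ref) / (abs(m_ref) + eps)
  out
}

#' Assemble the 13-feature set for one preprocessed trial
#'
#' Computes all features at the raw rate, then decimates them (and the
#' intensity trace) by `factor` to the analysis rate.  The kept samples are
#' aligned to the end of each decimation block so that every retained value
#' has a full block of raw data behind it.  Features that cannot be computed
#' (degenerate pulse or respiration) are masked rather than imputed.
#'
#' @param recording Preprocessed (filtered, trimmed) per-trial tibble with
#'   `gsr`, `pulse`, `rsp`, `intensity`.
#' @param fs Raw sampling rate in Hz.
#' @param factor Decimation factor (default 100, giving 2.56 Hz from
#'   256 Hz).
#' @param subject,trial,quality Metadata carried into the result.
#' @param rr_args List of arguments passed on to [running_rate()].
#' @return A [feature_set()].
#' @export
assemble_features <- function(recording, fs, factor = 100,
                              subject = NA_character_, trial = NA_integer_,
                              quality = NA_character_, rr_args = list()) {
  n <- nrow(recording)
  feats <- narx_feature_names()
  mask <- stats::setNames(rep(TRUE, length(feats)), feats)
  rr <- function(x) do.call(running_rate, c(list(x = x, fs = fs), rr_args))

  gsr <- recording$gsr
  raw <- list(
    gsr_filtered = gsr,
    gsr_deriv = derivative(gsr, fs),
    gsr_running_rate = rr(gsr)
  )

  hr <- heart_rate_series(recording$pulse, fs)
  if (is.null(hr)) {
    mask[c("hr_filtered", "hr_deriv", "hr_running_rate")] <- FALSE
    hr <- rep(NA_real_, n)
    raw$hr_filtered <- hr
    raw$hr_deriv <- hr
    raw$hr_running_rate <- hr
  } else {
    raw$hr_filtered <- hr
    raw$hr_deriv <- derivative(hr, fs)
    raw$hr_running_rate <- rr(hr)
  }

  cycles <- breath_segmentation(recording$rsp, fs)
  if (nrow(cycles) < 3) {
    rsp_cols <- c("rsp_rate", "rsp_rate_deriv", "rsp_running_rate",
                  "inspiration_time", "expiration_time", "inhalation_depth",
                  "exhalation_depth")
    mask[rsp_cols] <- FALSE
    for (cc in rsp_cols) raw[[cc]] <- rep(NA_real_, n)
  } else {
    bf <- breath_features(cycles, n, fs)
    raw$rsp_rate <- bf$rsp_rate
    raw$rsp_rate_deriv <- derivative(bf$rsp_rate, fs)
    raw$rsp_running_rate <- rr(bf$rsp_rate)
    raw$inspiration_time <- bf$inspiration_time
    raw$expiration_time <- bf$expiration_time
    raw$inhalation_depth <- bf$inhalation_depth
    raw$exhalation_depth <- bf$exhalation_depth
  }

  dec <- function(x) {
    if (all(is.na(x))) {
      x[seq(factor, n, by = factor)]
    } else {
      decimate(x, factor, phase = factor - 1L)
    }
  }
  out <- tibble::as_tibble(lapply(raw[feats], dec))
  out$intensity <- dec(recording$intensity)
  out$time_s <- (seq_len(nrow(out)) * factor - 1) / fs
  out <- out[, c("time_s", feats, "intensity")]
  feature_set(out, fs = fs / factor, mask = mask, subject = subject,
              trial = trial, quality = quality)
}

#' Run the full raw-to-features pipeline on a simulated dataset
#'
#' Filters, trims and featurises every analysed trial of a dataset produced
#' by [generate_recording()] or [simulate_dataset()].
#'
#' @param dataset Trial-level tibble with `recording` list-column.
#' @param keep_practice Keep practice trials (default drops them, mirroring
#'   the study analysis).
#' @param factor Decimation factor.
#' @param rr_args Arguments for [running_rate()].
#' @return The dataset tibble with a `features` list-column of
#'   [feature_set()] objects (practice trials removed unless requested).
#' @export
extract_dataset_features <- function(dataset, keep_practice = FALSE,
                                     factor = 100, rr_args = list()) {
  if (!keep_practice) dataset <- dplyr::filter(dataset, .data$analysed)
  dataset$features <- purrr::pmap(
    list(dataset$recording, dataset$fs, dataset$subject, dataset$trial,
         dataset$quality, dataset$annotations),
    function(rec, fs, subject, trial, quality, ann) {
      pp <- preprocess_trial(rec, fs, ann)
      assemble_features(pp$recording, fs, factor = factor, subject = subject,
                        trial = trial, quality = quality, rr_args = rr_args)
    }
  )
  dataset
}
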