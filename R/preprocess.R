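#' Filter specifications used by the preprocessing stage
#'
#' The conditioning chain mirrors typical biosignal-amplifier defaults:
#' GSR and pulse get a 30 Hz low-pass plus a 50 Hz mains notch; respiration
#' gets a 0.1--30 Hz band-pass plus the same notch.  All filters are applied
#' zero-phase (forward-backward) with odd-reflection edge padding.
#'
#' @param kind One of `"low-pass"`, `"band-pass"`, `"notch"`.
#' @param corners Corner frequency (Hz): length 1 for low-pass, 2 for
#'   band-pass.
#' @param notch_hz,notch_q Notch centre (Hz) and quality factor.
#' @param order Butterworth design order.
#' @param fs Sampling rate the spec will be designed for (validation only).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("low-pass", "band-pass", "notch"),
                        corners = NULL, notch_hz = 50, notch_q = 30,
                        order = 4, fs = 256) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (kind != "notch") {
    stopifnot(!is.null(corners), all(corners > 0), all(corners < nyq))
    if (kind == "band-pass") stopifnot(length(corners) == 2,
                                       corners[1] < corners[2])
  } else {
    stopifnot(notch_hz > 0, notch_hz < nyq, notch_q > 0)
  }
  structure(list(kind = kind, corners = corners, notch_hz = notch_hz,
                 notch_q = notch_q, order = order),
            class = "filter_spec")
}

# zero-phase filtering with odd-reflection padding at both edges
zero_phase <- function(b, a, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1, pad %||% (3 * max(length(a), length(b))))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# second-order IIR notch (RBJ biquad)
notch_coefs <- function(fs, f0 = 50, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Condition the GSR and pulse channels
#'
#' Zero-phase cascade of a 4th-order Butterworth low-pass at 30 Hz and a
#' 50 Hz notch (Q = 30).  Output length equals input length.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must exceed 100 Hz so that both corner
#'   frequencies are well inside the Nyquist band.
#' @param lp_hz,notch_hz Low-pass corner and notch centre in Hz.
#' @return Filtered numeric series.
#' @export
filter_cardio_eda <- function(x, fs, lp_hz = 30, notch_hz = 50) {
  if (fs <= 2 * lp_hz) abort("sampling rate must exceed twice the low-pass corner")
  bt <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  y <- zero_phase(bt$b, bt$a, x, pad = round(2 * fs))
  nc <- notch_coefs(fs, notch_hz)
  zero_phase(nc$b, nc$a, y, pad = round(2 * fs))
}

#' Condition the respiration channel
#'
#' Zero-phase band-pass 0.1--30 Hz (2nd-order high-pass cascaded with a
#' 4th-order low-pass, both Butterworth) followed by the 50 Hz notch.  The
#' cascade keeps the very low high-pass corner numerically well conditioned.
#'
#' @inheritParams filter_cardio_eda
#' @param hp_hz High-pass corner in Hz.
#' @return Filtered numeric series (mean approximately zero).
#' @export
filter_respiration <- function(x, fs, hp_hz = 0.1, lp_hz = 30,
                               notch_hz = 50) {
  if (fs <= 2 * lp_hz) abort("sampling rate must exceed twice the low-pass corner")
  hp <- signal::butter(2, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  y <- zero_phase(hp$b, hp$a, x, pad = round(10 * fs))
  y <- zero_phase(lp$b, lp$a, y, pad = round(2 * fs))
  nc <- notch_coefs(fs, notch_hz)
  zero_phase(nc$b, nc$a, y, pad = round(2 * fs))
}

#' Remove the first two seconds of a trial
#'
#' Participants needed a moment at trial onset to set the quality on the
#' reporting device, so the first 2 s of every channel and of the intensity
#' trace are discarded and the stimulus annotations re-referenced.  The
#' operation is deliberately not idempotent: a `trimmed` attribute guards
#' against applying it twice.
#'
#' @param recording A per-trial tibble (`time_s`, channels, `intensity`).
#' @param fs Sampling rate in Hz.
#' @param annotations Optional segment table to re-reference.
#' @param trim_s Seconds to discard (default 2).
#' @return A list with `recording` (trimmed tibble, `time_s` restarted at 0,
#'   attribute `trimmed = TRUE`) and `annotations`.
#' @export
trim_trial <- function(recording, fs, annotations = NULL, trim_s = 2) {
  if (isTRUE(attr(recording, "trimmed"))) {
    abort("recording already trimmed; the trim is applied exactly once")
  }
  n_cut <- round(trim_s * fs)
  if (nrow(recording) <= n_cut) abort("trial not longer than the trim window")
  out <- recording[-seq_len(n_cut), , drop = FALSE]
  if ("time_s" %in% names(out)) out$time_s <- out$time_s - trim_s
  attr(out, "trimmed") <- TRUE
  if (!is.null(annotations)) {
    annotations$onset_s <- annotations$onset_s - trim_s
    annotations$offset_s <- annotations$offset_s - trim_s
  }
  list(recording = out, annotations = annotations)
}

#' Decimate a series by an integer factor
#'
#' Anti-alias low-pass (zero-phase Butterworth at 80% of the new Nyquist)
#' followed by keeping every `factor`-th sample starting at `phase`
#' (0-based).  With `phase = 0` the output length is `ceiling(n / factor)`;
#' with `phase = factor - 1` it is `floor(n / factor)`, which aligns every
#' kept sample to the end of a full decimation block.
#'
#' @param x Numeric series.
#' @param factor Integer decimation factor (>= 1).
#' @param phase 0-based offset of the first kept sample.
#' @return Numeric series; attribute `rate_divisor` records the factor.
#' @export
#' @examples
#' length(decimate(rep(1, 1000), 100)) # 10
decimate <- function(x, factor, phase = 0) {
  if (factor != round(factor) || factor < 1) {
    abort("decimation factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (length(x) < factor) abort("series shorter than the decimation factor")
  if (factor == 1L) return(x)
  bt <- signal::butter(4, 0.8 / factor, type = "low")
  y <- zero_phase(bt$b, bt$a, x, pad = min(length(x) - 1, 30 * factor))
  out <- y[seq(1L + phase, length(y), by = factor)]
  attr(out, "rate_divisor") <- factor
  out
}

#' Preprocess one trial end to end
#'
#' Applies the channel-specific filters, trims the first 2 s, and records a
#' provenance attribute.  Feature extraction (and the subsequent decimation
#' of the feature series) happens downstream in [assemble_features()].
#'
#' @param recording Per-trial tibble with `gsr`, `pulse`, `rsp`,
#'   `intensity`.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional stimulus segment table.
#' @return A list with `recording`, `annotations` and `provenance`.
#' @export
preprocess_trial <- function(recording, fs, annotations = NULL) {
  rec <- recording
  rec$gsr <- filter_cardio_eda(rec$gsr, fs)
  rec$pulse <- filter_cardio_eda(rec$pulse, fs)
  rec$rsp <- filter_respiration(rec$rsp, fs)
  out <- trim_trial(rec, fs, annotations)
  out$provenance <- list(
    filters = c("low-pass 30 Hz + notch 50 Hz (gsr, pulse)",
                "band-pass 0.1-30 Hz + notch 50 Hz (rsp)"),
    trimmed_s = 2, fs = fs
  )
  out
}
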