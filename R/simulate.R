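#' Subject-level physiological response profile
#'
#' Parameters of the synthetic physiology: tonic skin-conductance level and
#' drift, stimulus-locked skin-conductance-response (SCR) kernel (amplitude
#' gain, bi-exponential rise/decay), cardiac baseline and stimulus coupling,
#' respiratory baseline and coupling, per-channel measurement noise, and the
#' dynamics of the intensity knob (pure lag plus first-order smoothing).
#'
#' @param gsr_baseline_us Tonic skin conductance in microsiemens.
#' @param gsr_drift_us_min Slow tonic drift in microsiemens per minute.
#' @param scr_gain_us SCR peak amplitude (microsiemens) per unit nominal
#'   image intensity.
#' @param scr_rise_s,scr_decay_s Bi-exponential SCR rise and decay time
#'   constants in seconds.
#' @param hr_rest_bpm Resting heart rate, beats per minute (must lie in
#'   40--120).
#' @param hr_gain_bpm HR increase (bpm) per unit stimulus drive.
#' @param hr_latency_s Latency of the cardiac response to the stimulus.
#' @param hr_var_bpm Standard deviation of spontaneous heart-rate
#'   variability (slow fluctuations around the resting rate).
#' @param rsp_rest_bpm Resting respiration rate, breaths per minute (6--30).
#' @param rsp_depth Resting breathing amplitude (arbitrary units).
#' @param rsp_rate_gain_bpm,rsp_depth_gain Stimulus modulation of breathing
#'   rate (breaths/min per unit drive) and relative depth.
#' @param rsp_var_bpm Standard deviation of spontaneous breathing-rate
#'   variability.
#' @param var_tau_s Correlation time of the spontaneous rate fluctuations.
#' @param noise_gsr,noise_pulse,noise_rsp Measurement-noise standard
#'   deviations per channel.
#' @param knob_lag_s Pure reaction lag of the intensity knob in seconds.
#' @param knob_tau_s First-order smoothing constant of the knob in seconds.
#'
#' @return An object of class `subject_profile` (a named list).
#' @export
subject_profile <- function(gsr_baseline_us = 5, gsr_drift_us_min = 0.05,
                            scr_gain_us = 0.8,
                            scr_rise_s = 0.75, scr_decay_s = 2.5,
                            hr_rest_bpm = 70, hr_gain_bpm = 10,
                            hr_latency_s = 1, hr_var_bpm = 2,
                            rsp_rest_bpm = 15, rsp_depth = 1,
                            rsp_rate_gain_bpm = 4, rsp_depth_gain = 0.3,
                            rsp_var_bpm = 1, var_tau_s = 8,
                            noise_gsr = 0.02, noise_pulse = 0.05,
                            noise_rsp = 0.05,
                            knob_lag_s = 0.5, knob_tau_s = 2) {
  p <- as.list(environment())
  if (!all(vapply(p, is.finite, logical(1)))) {
    abort("all profile parameters must be finite")
  }
  if (hr_rest_bpm < 40 || hr_rest_bpm > 120) {
    abort("resting HR must lie in [40, 120] bpm")
  }
  if (rsp_rest_bpm < 6 || rsp_rest_bpm > 30) {
    abort("resting respiration rate must lie in [6, 30] breaths/min")
  }
  if (scr_rise_s <= 0 || scr_decay_s <= scr_rise_s) {
    abort("SCR kernel needs 0 < rise < decay")
  }
  structure(p, class = "subject_profile")
}

#' Draw a randomised subject profile
#'
#' Jitters the [subject_profile()] defaults multiplicatively so that a
#' simulated population shows realistic between-subject variation in tonic
#' levels, response gains and noise.
#'
#' @param seed Integer seed.
#' @return A `subject_profile`.
#' @export
sample_subject_profile <- function(seed) {
  with_seed(seed, {
    jit <- function(x, cv = 0.15) x * exp(rnorm(1, 0, cv))
    subject_profile(
      gsr_baseline_us = jit(5, 0.2),
      scr_gain_us = jit(0.8, 0.25),
      scr_rise_s = jit(0.75, 0.1), scr_decay_s = jit(2.5, 0.1),
      hr_rest_bpm = min(120, max(40, 70 + rnorm(1, 0, 6))),
      hr_gain_bpm = jit(10, 0.25), hr_latency_s = jit(1, 0.2),
      hr_var_bpm = jit(2, 0.2),
      rsp_rest_bpm = min(30, max(6, 15 + rnorm(1, 0, 2))),
      rsp_rate_gain_bpm = jit(4, 0.25), rsp_depth_gain = jit(0.3, 0.25),
      rsp_var_bpm = jit(1, 0.2),
      noise_gsr = jit(0.02, 0.2), noise_pulse = jit(0.05, 0.2),
      noise_rsp = jit(0.05, 0.2),
      knob_lag_s = jit(0.5, 0.2), knob_tau_s = jit(2, 0.2)
    )
  })
}

# nominal stimulus drive: image level during each image segment, 0 elsewhere
stimulus_drive <- function(t, segments, image_levels) {
  drive <- numeric(length(t))
  img <- segments[grepl("^image", segments$segment), ]
  for (i in seq_len(nrow(img))) {
    sel <- t >= img$onset_s[i] & t < img$offset_s[i]
    drive[sel] <- image_levels[[i]]
  }
  drive
}

# bi-exponential SCR kernel, peak-normalised to 1
scr_kernel <- function(tau, rise, decay) {
  k <- exp(-tau / decay) - exp(-tau / rise)
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  k_peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  k / k_peak
}

#' Generate raw recordings for one subject
#'
#' Synthesises the three physiological channels plus the continuous
#' intensity trace for every trial in a timeline:
#' * **gsr** — tonic level + drift + stimulus-locked bi-exponential SCRs
#'   whose amplitude grows with the nominal image intensity, plus noise;
#' * **pulse** — a quasi-periodic peaked waveform whose instantaneous rate
#'   is the resting HR plus a lagged stimulus drive plus slow spontaneous
#'   heart-rate variability;
#' * **rsp** — a sinusoid with rate and depth modulated by the drive, the
#'   rate carrying its own slow spontaneous variability;
#' * **intensity** — a first-order lagged, saturating knob response to the
#'   nominal image intensity, clipped to `[0, 1]`.
#'
#' @param timeline A timeline from [generate_protocol()].
#' @param profile A [subject_profile()].
#' @param config The [protocol_config()] used to build the timeline.
#' @param seed Integer seed for channel noise.
#' @param subject Subject identifier stored with each trial.
#'
#' @return A tibble with one row per trial (`subject`, `trial`, `quality`,
#'   `practice`, `analysed`, `fs`) and list-columns `recording` (tibble of
#'   `time_s`, `gsr`, `pulse`, `rsp`, `intensity`) and `annotations`
#'   (stimulus segments with nominal levels).
#' @export
#' @examples
#' cfg <- protocol_config(trials_per_quality = 2, qualities = "Q1")
#' tl <- generate_protocol(cfg)
#' rec <- generate_recording(tl, subject_profile(), cfg, seed = 1)
generate_recording <- function(timeline, profile, config, seed = 1L,
                               subject = "S01") {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "protocol_config"))
  fs <- config$fs_raw
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(timeline)), function(i) {
      simulate_trial(timeline[i, ], profile, fs)
    })
  })
  out <- dplyr::select(timeline, "trial", "quality", "practice", "analysed")
  out$subject <- subject
  out$fs <- fs
  out$recording <- lapply(rows, `[[`, "recording")
  out$annotations <- lapply(rows, `[[`, "annotations")
  dplyr::select(out, "subject", "trial", "quality", "practice", "analysed",
                "fs", "recording", "annotations")
}

# one trial's channels at the raw rate; RNG state is managed by the caller
simulate_trial <- function(trial_row, profile, fs) {
  segments <- trial_row$segments[[1]]
  levels <- trial_row$image_levels[[1]]
  dur <- trial_row$duration_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  drive <- stimulus_drive(t, segments, levels)

  # --- electrodermal channel ---
  gsr <- profile$gsr_baseline_us + profile$gsr_drift_us_min * t / 60
  img <- segments[grepl("^image", segments$segment), ]
  for (i in seq_len(nrow(img))) {
    tau <- t - img$onset_s[i]
    on <- tau >= 0
    gsr[on] <- gsr[on] + profile$scr_gain_us * levels[[i]] *
      scr_kernel(tau[on], profile$scr_rise_s, profile$scr_decay_s)
  }
  gsr <- gsr + rnorm(n, 0, profile$noise_gsr)

  # slow spontaneous rate fluctuations (AR(1) with correlation time var_tau_s)
  slow_noise <- function(sd_target) {
    if (sd_target <= 0) return(numeric(n))
    rho <- exp(-1 / (profile$var_tau_s * fs))
    v <- stats::filter(rnorm(n, 0, sqrt(1 - rho^2)), rho, "recursive")
    as.numeric(v) * sd_target
  }

  # --- cardiac channel: peaked periodic waveform at a drive-modulated rate
  lag_n <- round(profile$hr_latency_s * fs)
  drive_lag <- c(rep(0, lag_n), drive)[seq_len(n)]
  hr_inst <- profile$hr_rest_bpm + profile$hr_gain_bpm * drive_lag +
    slow_noise(profile$hr_var_bpm)
  phase <- 2 * pi * cumsum(hr_inst / 60) / fs
  pulse <- exp(3 * (cos(phase) - 1)) + rnorm(n, 0, profile$noise_pulse)

  # --- respiratory channel ---
  rsp_rate_inst <- profile$rsp_rest_bpm + profile$rsp_rate_gain_bpm * drive +
    slow_noise(profile$rsp_var_bpm)
  rphase <- 2 * pi * cumsum(rsp_rate_inst / 60) / fs
  depth <- profile$rsp_depth * (1 + profile$rsp_depth_gain * drive)
  rsp <- depth * sin(rphase) + rnorm(n, 0, profile$noise_rsp)

  # --- intensity knob: pure lag + first-order smoothing toward the level
  klag <- round(profile$knob_lag_s * fs)
  target <- c(rep(0, klag), drive)[seq_len(n)]
  alpha <- 1 - exp(-1 / (profile$knob_tau_s * fs))
  intensity <- numeric(n)
  for (k in 2:n) {
    intensity[k] <- intensity[k - 1] + alpha * (target[k] - intensity[k - 1])
  }
  intensity <- pmin(1, pmax(0, intensity))

  ann <- segments
  ann$level <- 0
  ann$level[grepl("^image", ann$segment)] <- unlist(levels)
  list(
    recording = tibble::tibble(time_s = t, gsr = gsr, pulse = pulse,
                               rsp = rsp, intensity = intensity),
    annotations = ann
  )
}

#' Simulate a multi-subject dataset
#'
#' Convenience wrapper: per-subject randomised profiles and timelines under
#' one master seed.
#'
#' @param config A [protocol_config()].
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A tibble of trials across subjects (see [generate_recording()]).
#' @export
simulate_dataset <- function(config = protocol_config(), seed = 1L) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      2 * config$n_subjects))
  purrr::map_dfr(seq_len(config$n_subjects), function(s) {
    tl <- generate_protocol(config, seed = seeds[2 * s - 1])
    prof <- sample_subject_profile(seeds[2 * s])
    generate_recording(tl, prof, config, seed = seeds[2 * s],
                       subject = sprintf("S%02d", s))
  })
}

#' A known NARX generating process
#'
#' Ground-truth difference equation used in parameter-recovery experiments:
#' linear output lags, linear and quadratic input lags per feature, plus an
#' innovation (equation-error) term.
#'
#' @param spec A [lag_spec()] naming the features and their lag structure.
#' @param a Coefficients of the output lags `y(t-1) ... y(t-n_y)`.
#' @param b_lin List (one element per feature) of linear input coefficients,
#'   each of length `n_u + 1` (lags `n_k ... n_k + n_u`).
#' @param b_quad Like `b_lin` for the squared input terms.
#' @param c0 Intercept.
#' @param noise_sd Innovation standard deviation.
#' @param bound Divergence guard: simulation aborts if `|y|` exceeds it.
#' @return An object of class `true_narx_process`.
#' @export
true_narx_process <- function(spec, a, b_lin, b_quad = NULL, c0 = 0,
                              noise_sd = 0, bound = 1e3) {
  stopifnot(inherits(spec, "lag_spec"), length(a) == spec$n_y)
  m <- length(spec$features)
  stopifnot(length(b_lin) == m)
  b_quad <- b_quad %||% lapply(spec$n_u + 1, numeric)
  for (j in seq_len(m)) {
    stopifnot(length(b_lin[[j]]) == spec$n_u[j] + 1,
              length(b_quad[[j]]) == spec$n_u[j] + 1)
  }
  structure(list(spec = spec, a = a, b_lin = b_lin, b_quad = b_quad,
                 c0 = c0, noise_sd = noise_sd, bound = bound),
            class = "true_narx_process")
}

#' Generate an intensity series from a known NARX process
#'
#' Applies the generating recursion exactly: initial outputs are zero, each
#' subsequent value combines the linear output lags with linear and
#' quadratic input lags of the named features, plus seeded innovation noise.
#' Returns both the raw series and a min-max scaled copy in `[0, 1]` that can
#' stand in for a knob-style ground truth.
#'
#' @param features A [feature_set()] (or plain tibble of feature columns)
#'   supplying the exogenous inputs.
#' @param proc A [true_narx_process()].
#' @param seed Integer seed for the innovation noise.
#' @return A tibble with columns `y_raw` and `y_scaled`.
#' @export
generate_intensity_from_narx <- function(features, proc, seed = 1L) {
  stopifnot(inherits(proc, "true_narx_process"))
  U <- feature_matrix(features, proc$spec$features)
  spec <- proc$spec
  n <- nrow(U)
  maxlook <- max(spec$n_y, max(spec$n_k + spec$n_u))
  if (n <= maxlook) abort("feature series shorter than the maximum lookback")
  e <- if (proc$noise_sd > 0) {
    with_seed(seed, rnorm(n, 0, proc$noise_sd))
  } else {
    numeric(n)
  }
  y <- numeric(n)
  for (t in (maxlook + 1):n) {
    val <- proc$c0 + sum(proc$a * y[t - seq_len(spec$n_y)])
    for (j in seq_along(spec$features)) {
      lags <- spec$n_k[j] + 0:spec$n_u[j]
      u <- U[t - lags, j]
      val <- val + sum(proc$b_lin[[j]] * u) + sum(proc$b_quad[[j]] * u^2)
    }
    val <- val + e[t]
    if (!is.finite(val) || abs(val) > proc$bound) {
      abort(sprintf("generating recursion unstable at t=%d (|y|=%.3g)",
                    t, abs(val)))
    }
    y[t] <- val
  }
  rng <- range(y)
  scaled <- if (diff(rng) > 0) (y - rng[1]) / diff(rng) else rep(0, n)
  tibble::tibble(y_raw = y, y_scaled = scaled)
}

#' Reference ground-truth coupling process and benchmark subjects
#'
#' `narx_ground_truth_process()` defines the package's canonical
#' parameter-recovery benchmark: emotion intensity generated by a stable
#' NARX difference equation driven by the filtered skin conductance and the
#' respiration rate, with linear + quadratic input terms and moderate
#' innovation noise (the coefficients are balanced against the natural
#' scales of the two features so both contribute materially).
#' `simulate_coupled_subject()` simulates one subject under the standard
#' protocol, extracts the 13 features, and replaces the knob intensity of
#' every analysed trial with the min-max-scaled output of that process —
#' yielding trials whose intensity is *dynamically* coupled to the
#' physiology with a known lag structure.
#'
#' @param n_k True input delays of the two features.
#' @param bounds Lag bounds the recovery experiment will search over (the
#'   true lags must lie inside).
#' @param noise_sd Innovation standard deviation.
#' @return For `narx_ground_truth_process()`: a [true_narx_process()].
#' @export
narx_ground_truth_process <- function(n_k = c(2L, 2L), bounds = c(1L, 4L),
                                      noise_sd = 0.3) {
  # every covered lag carries a material coefficient, so the onset of the
  # input window (the delay n_k) is identifiable to within one lag: any
  # competing window must cover the same lags to reach the same fit
  spec <- lag_spec(2, c("gsr_filtered", "rsp_rate"), n_u = c(2L, 2L),
                   n_k = n_k, bounds = bounds)
  true_narx_process(
    spec, a = c(0.4, 0.2),
    b_lin = list(c(1.2, 1.2, 1.2), c(0.12, 0.12, 0.12)),
    b_quad = list(c(0.05, 0, 0), c(0, 0, 0)),
    noise_sd = noise_sd
  )
}

#' @rdname narx_ground_truth_process
#' @param seed Integer seed (protocol order, profile, channel noise and
#'   innovation noise all derive from it).
#' @param process A [true_narx_process()] supplying the coupling.
#' @param subject Subject identifier.
#' @param quality Quality label of the simulated trials.
#' @return For `simulate_coupled_subject()`: a list of 7 [feature_set()]
#'   trials.
#' @export
simulate_coupled_subject <- function(seed,
                                     process = narx_ground_truth_process(),
                                     subject = "S01", quality = "Q1") {
  cfg <- protocol_config(n_subjects = 1, qualities = quality,
                         trials_per_quality = 8, seed = seed)
  tl <- generate_protocol(cfg, seed = seed)
  prof <- sample_subject_profile(seed + 1000L)
  ds <- generate_recording(tl, prof, cfg, seed = seed + 2000L,
                           subject = subject)
  trials <- extract_dataset_features(ds)$features
  lapply(seq_along(trials), function(i) {
    f <- trials[[i]]
    f$data$intensity <- generate_intensity_from_narx(
      f, process, seed = seed + i)$y_scaled
    f
  })
}
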