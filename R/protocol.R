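#' Study protocol configuration
#'
#' Describes the picture-viewing protocol that the synthetic-data generator
#' emulates: 21 subjects, 3 emotion qualities, 8 trials per quality (the
#' first of each quality is a practice trial and is excluded from analysis).
#' Each trial consists of a 2 s "new trial" cue, three 15 s emotional images,
#' a 30 s black screen and a 30 s neutral image, for 107 s per trial and
#' roughly 43 minutes overall.  Signals are acquired at 256 Hz so that
#' decimation by 100 later yields the 2.56 Hz feature rate.
#'
#' @param n_subjects Number of subjects (default 21).
#' @param qualities Character vector of emotion-quality labels.
#' @param trials_per_quality Trials per quality, including one practice
#'   trial (default 8).
#' @param cue_s,image_s,black_s,neutral_s Segment durations in seconds.
#' @param n_images Number of emotional images per trial.
#' @param fs_raw Acquisition rate in Hz.
#' @param image_levels Discrete set of nominal image-intensity levels in
#'   `[0, 1]`; each trial presents a random permutation of these levels.
#' @param seed Integer seed controlling trial order and image levels.
#'
#' @return An object of class `protocol_config` (a named list).
#' @export
#' @examples
#' cfg <- protocol_config()
#' trial_duration_s(cfg) # 107
protocol_config <- function(n_subjects = 21,
                            qualities = c("Q1", "Q2", "Q3"),
                            trials_per_quality = 8,
                            cue_s = 2, image_s = 15, n_images = 3,
                            black_s = 30, neutral_s = 30,
                            fs_raw = 256,
                            image_levels = c(0.3, 0.6, 0.9),
                            seed = 1L) {
  stopifnot(length(qualities) >= 1, !anyDuplicated(qualities))
  if (n_subjects < 1 || trials_per_quality < 2) {
    abort("need at least 1 subject and 2 trials per quality (one is practice)")
  }
  durs <- c(cue_s = cue_s, image_s = image_s, black_s = black_s,
            neutral_s = neutral_s)
  if (any(durs <= 0) || n_images < 1 || fs_raw <= 0) {
    abort("all durations, image count and sampling rate must be positive")
  }
  if (any(image_levels < 0 | image_levels > 1)) {
    abort("image levels must lie in [0, 1]")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      qualities = as.character(qualities),
      trials_per_quality = as.integer(trials_per_quality),
      cue_s = cue_s, image_s = image_s, n_images = as.integer(n_images),
      black_s = black_s, neutral_s = neutral_s,
      fs_raw = fs_raw,
      image_levels = image_levels,
      seed = as.integer(seed)
    ),
    class = "protocol_config"
  )
}

#' @rdname protocol_config
#' @param config A `protocol_config`.
#' @export
trial_duration_s <- function(config) {
  config$cue_s + config$n_images * config$image_s + config$black_s +
    config$neutral_s
}

#' Generate the study timeline
#'
#' Lays out the ordered trial sequence for one subject: one fixed practice
#' trial per quality first (familiarisation), then the analysed trials in a
#' seeded random order.  Each trial carries a random permutation of the
#' nominal image-intensity levels and the segment boundaries (cue, images,
#' black screen, neutral image) in seconds from trial onset.
#'
#' @param config A [protocol_config()].
#' @param seed Optional integer overriding `config$seed`.
#'
#' @return A tibble with one row per trial: `trial`, `quality`, `practice`,
#'   `analysed`, `duration_s`, list-columns `image_levels` (numeric,
#'   one level per image) and `segments` (tibble of segment name,
#'   onset/offset seconds).
#' @export
#' @examples
#' tl <- generate_protocol(protocol_config())
#' nrow(tl)            # 24 trials
#' sum(tl$analysed)    # 21 analysed, 7 per quality
generate_protocol <- function(config, seed = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  seed <- seed %||% config$seed
  qualities <- config$qualities
  n_per <- config$trials_per_quality

  with_seed(seed, {
    practice <- tibble::tibble(quality = qualities, practice = TRUE)
    rest <- tibble::tibble(
      quality = rep(qualities, each = n_per - 1L),
      practice = FALSE
    )
    rest <- rest[sample.int(nrow(rest)), ]
    tl <- dplyr::bind_rows(practice, rest)
    tl$trial <- seq_len(nrow(tl))
    tl$analysed <- !tl$practice
    tl$duration_s <- trial_duration_s(config)
    tl$image_levels <- lapply(seq_len(nrow(tl)), function(i) {
      sample(config$image_levels, config$n_images,
             replace = config$n_images > length(config$image_levels))
    })
    tl$segments <- lapply(seq_len(nrow(tl)), function(i) {
      trial_segments(config)
    })
    dplyr::select(
      tl, "trial", "quality", "practice", "analysed", "duration_s",
      "image_levels", "segments"
    )
  })
}

# per-trial segment table (onset/offset in seconds from trial start)
trial_segments <- function(config) {
  names <- c("cue", paste0("image", seq_len(config$n_images)), "black",
             "neutral")
  durs <- c(config$cue_s, rep(config$image_s, config$n_images),
            config$black_s, config$neutral_s)
  offs <- cumsum(durs)
  tibble::tibble(segment = names, onset_s = c(0, head(offs, -1)),
                 offset_s = offs)
}
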