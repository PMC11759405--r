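#' Write and read recording datasets as plain text
#'
#' A dataset directory holds one long-format CSV per subject
#' (`subject, trial, time_s, channel, value`) plus a `manifest.json`
#' recording the sampling rate, trial metadata and stimulus annotations.
#' The round trip is lossless up to numeric printing precision
#' (`write_recordings()` prints at full double precision).
#'
#' @param dataset Trial-level tibble from [generate_recording()] or
#'   [simulate_dataset()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- c("gsr", "pulse", "rsp", "intensity")
  manifest <- list(
    subjects = list(),
    channels = channels
  )
  for (s in unique(dataset$subject)) {
    rows <- dataset[dataset$subject == s, ]
    long <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      rec <- rows$recording[[i]]
      tidyr::pivot_longer(
        dplyr::mutate(rec, subject = s, trial = rows$trial[i]),
        dplyr::all_of(channels), names_to = "channel", values_to = "value"
      )[, c("subject", "trial", "time_s", "channel", "value")]
    })
    readr::write_csv(long, file.path(dir, paste0(s, ".csv")))
    manifest$subjects[[s]] <- list(
      file = paste0(s, ".csv"),
      trials = lapply(seq_len(nrow(rows)), function(i) {
        list(trial = rows$trial[i], quality = rows$quality[i],
             practice = rows$practice[i], fs = rows$fs[i],
             annotations = rows$annotations[[i]])
      })
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_recordings
#' @param path A dataset directory written by [write_recordings()].
#' @return For `load_recordings()`: the trial-level tibble (a trial whose
#'   CSV lacks the `rsp` channel is loaded with the respiration-derived
#'   features destined to be masked downstream; schema violations raise
#'   errors naming the subject and trial).
#' @export
load_recordings <- function(path) {
  mf_file <- file.path(path, "manifest.json")
  if (!file.exists(mf_file)) abort("no manifest.json in dataset directory")
  manifest <- jsonlite::read_json(mf_file)
  channels <- unlist(manifest$channels)
  out <- list()
  for (s in names(manifest$subjects)) {
    entry <- manifest$subjects[[s]]
    csv <- file.path(path, entry$file)
    if (!file.exists(csv)) abort(sprintf("subject %s: missing file %s", s,
                                         entry$file))
    long <- readr::read_csv(csv, col_types = "cidcd", progress = FALSE)
    for (tr in entry$trials) {
      t_id <- tr$trial
      sub <- long[long$trial == t_id, ]
      if (!nrow(sub)) abort(sprintf("subject %s trial %s: no samples", s, t_id))
      wide <- tidyr::pivot_wider(sub, id_cols = "time_s",
                                 names_from = "channel",
                                 values_from = "value")
      missing_core <- setdiff(c("gsr", "pulse", "intensity"), names(wide))
      if (length(missing_core)) {
        abort(sprintf("subject %s trial %s: missing channel(s) %s", s, t_id,
                      paste(missing_core, collapse = ", ")))
      }
      if (!"rsp" %in% names(wide)) wide$rsp <- 0 # degenerate: masked downstream
      fs <- tr$fs
      if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
        abort(sprintf("subject %s trial %s: corrupted fs attribute", s, t_id))
      }
      ann <- tr$annotations
      ann_tb <- if (is.null(ann)) NULL else tibble::as_tibble(
        lapply(ann, unlist))
      out[[length(out) + 1]] <- tibble::tibble(
        subject = s, trial = as.integer(t_id),
        quality = tr$quality %||% NA_character_,
        practice = isTRUE(tr$practice),
        analysed = !isTRUE(tr$practice), fs = fs,
        recording = list(wide[, c("time_s", "gsr", "pulse", "rsp",
                                  "intensity")]),
        annotations = list(ann_tb)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Run configuration
#'
#' A serialisable bundle of every knob a full analysis run needs: the
#' protocol, filter corners, running-rate windows, search bounds and GA
#' settings, the selection threshold and cap, evaluation mode flags, and
#' the master seed.  A stable hash of the configuration is recorded so any
#' output can be traced back to the exact settings.
#'
#' @param protocol A [protocol_config()] (stored as a plain list).
#' @param bounds Integer lag-search bounds.
#' @param delta Forward-selection improvement threshold.
#' @param max_features NARX feature cap.
#' @param ga_pop,ga_mut,ga_cross GA population size and operator rates.
#' @param running_rate_windows Eval/ref/gap windows in seconds.
#' @param intersubject_mode `"paper"` or `"holdout"`.
#' @param seed Master seed.
#' @return A list of class `run_config` with a `hash` field.
#' @export
run_config <- function(protocol = protocol_config(), bounds = c(1L, 11L),
                       delta = 0.01, max_features = 3,
                       ga_pop = 50, ga_mut = 0.1, ga_cross = 0.8,
                       running_rate_windows = c(eval = 5, ref = 10, gap = 5),
                       intersubject_mode = "paper", seed = 1L) {
  cfg <- list(
    protocol = unclass(protocol), bounds = bounds, delta = delta,
    max_features = max_features, ga_pop = ga_pop, ga_mut = ga_mut,
    ga_cross = ga_cross, running_rate_windows = running_rate_windows,
    intersubject_mode = intersubject_mode, seed = seed
  )
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# order-independent content hash of a plain list (djb2 over the YAML dump)
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg[sort(names(cfg))])
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param file Path of the YAML file.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  stored <- cfg$hash
  cfg$hash <- NULL
  cfg$hash <- config_hash(cfg)
  if (!is.null(stored) && !identical(stored, cfg$hash)) {
    warn("configuration hash mismatch: file was edited after writing")
  }
  cfg$protocol <- do.call(protocol_config, cfg$protocol[
    setdiff(names(cfg$protocol), character(0))])
  structure(cfg, class = "run_config")
}
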