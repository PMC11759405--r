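#' Load the published per-participant result tables
#'
#' The study's raw recordings are not deposited, but its per-participant
#' summary tables are printed in full; they ship with the package as plain
#' CSV fixtures.  `intra` holds the subject-dependent results for the three
#' emotion qualities: one row per selection stage, participant and model
#' kind (`narx` or `lr`), with the feature added at that stage and the mean
#' LOOCV correlation reached.  `inter` holds the intersubject results: one
#' row per random train/test split (and per feature combination for the
#' third quality), with the optimised lag parameters and the mean test
#' correlation.
#'
#' @return A list with tibbles `intra` and `inter`.
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' dplyr::filter(fx$intra, participant == "012", quality == "Q1",
#'               model == "narx")
load_paper_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "narxaffect",
                                  mustWork = TRUE)
  intra <- readr::read_csv(path("intrasubject_tables.csv"),
                           col_types = "cccicd", progress = FALSE)
  inter <- readr::read_csv(path("intersubject_tables.csv"),
                           col_types = "cicccccd", progress = FALSE)
  validate_fixtures(intra, inter)
  inter$params <- lapply(inter$params, function(p) {
    if (is.na(p) || p == "") integer(0) else
      as.integer(strsplit(p, " ", fixed = TRUE)[[1]])
  })
  inter$train <- strsplit(inter$train, ";", fixed = TRUE)
  inter$test <- strsplit(inter$test, ";", fixed = TRUE)
  list(intra = intra, inter = inter)
}

# structural integrity checks: a malformed fixture should fail loudly
validate_fixtures <- function(intra, inter) {
  feats <- narx_feature_names()
  ok <- TRUE
  msg <- character(0)
  for (q in c("Q1", "Q2", "Q3")) {
    for (m in c("narx", "lr")) {
      n <- length(unique(intra$participant[intra$quality == q &
                                             intra$model == m]))
      if (n != 21) {
        ok <- FALSE
        msg <- c(msg, sprintf("%s/%s: %d participants (expected 21)", q, m, n))
      }
    }
  }
  if (!all(intra$feature %in% feats)) {
    ok <- FALSE
    msg <- c(msg, "unknown feature name in intrasubject fixture")
  }
  if (any(abs(intra$r) > 1) || any(abs(inter$mean_r) > 1)) {
    ok <- FALSE
    msg <- c(msg, "correlation outside [-1, 1]")
  }
  narx_rows <- intra$model == "narx"
  if (any(table(intra$participant[narx_rows], intra$quality[narx_rows]) > 3)) {
    ok <- FALSE
    msg <- c(msg, "more than 3 NARX features for a participant")
  }
  if (!ok) abort(paste(c("fixture integrity check failed:", msg),
                       collapse = "\n  "))
  invisible(TRUE)
}

#' Best (final-stage) correlations per participant from the fixtures
#'
#' @param intra The `intra` tibble of [load_paper_fixtures()].
#' @param which_quality,which_model Filters.
#' @return A tibble `participant`, `features` (list-column of the full
#'   optimal set), `best_r`.
#' @export
fixture_best_results <- function(intra, which_quality, which_model) {
  sub <- dplyr::filter(intra, .data$quality == which_quality,
                       .data$model == which_model)
  sub <- dplyr::arrange(sub, .data$participant, .data$stage)
  dplyr::summarise(
    dplyr::group_by(sub, .data$participant),
    features = list(.data$feature),
    best_r = .data$r[dplyr::n()],
    .groups = "drop"
  )
}
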