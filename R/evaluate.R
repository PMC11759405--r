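#' Mean leave-one-out correlation of a lag spec
#'
#' The score the lag searches optimise: each of a subject's trials serves
#' once as the test trial while the model is fitted on the remaining ones;
#' the per-fold Pearson correlations between the (free-run, by default)
#' prediction and the ground-truth intensity are averaged.  A fold whose
#' free-run simulation diverges makes the whole spec score `-Inf`, so the
#' searches steer away from unstable structures.
#'
#' @param trials List of [feature_set()] objects, one per trial.
#' @param spec A [lag_spec()].
#' @param control A [narx_control()].
#' @param mode Simulation mode passed to [simulate_narx()].
#' @param seed Seed forwarded to [fit_narx()].
#' @return A list with `mean_r` and `fold_r` (one correlation per trial).
#' @export
loocv_score <- function(trials, spec, control = narx_control(),
                        mode = "free_run", seed = 1L) {
  stopifnot(length(trials) >= 2)
  built <- lapply(trials, build_regressors, spec = spec)
  fold_r <- vapply(seq_along(trials), function(i) {
    model <- fit_narx_built(built[-i], spec, control, seed = seed)
    sim <- simulate_narx(model, trials[[i]], mode = mode)
    pearson_r(sim$y_hat, sim$y_true)
  }, numeric(1))
  list(mean_r = mean(fold_r), fold_r = fold_r)
}

# stage evaluator for NARX forward selection: exhaustive search for one
# feature, GA for two or three
narx_stage_evaluator <- function(trials, control = narx_control(n_units = 0),
                                 bounds = c(1L, 11L), ga = NULL,
                                 mode = "free_run", seed = 1L) {
  force(trials)
  function(feats) {
    m <- length(feats)
    inner <- function(par) {
      spec <- lag_spec_from_par(par, feats, bounds = bounds)
      loocv_score(trials, spec, control = control, mode = mode,
                  seed = seed)$mean_r
    }
    if (m == 1) {
      res <- exhaustive_lag_search(inner, bounds = bounds)
    } else {
      n_par <- 1L + 2L * m
      cfg <- ga %||% ga_config(n_par)
      if (cfg$n_params != n_par) cfg <- ga_config(n_par,
        pop_size = cfg$pop_size, p_cross = cfg$p_cross, p_mut = cfg$p_mut,
        elite = cfg$elite, stall_window = cfg$stall_window,
        stall_tol = cfg$stall_tol, tournament = cfg$tournament,
        max_generations = cfg$max_generations)
      res <- ga_lag_search(inner, n_par, config = cfg, bounds = bounds,
                           seed = seed)
    }
    list(score = res$score,
         spec = lag_spec_from_par(res$par, feats, bounds = bounds),
         detail = res)
  }
}

# stage evaluator for the sliding-window LR: plain refit per fold
lr_stage_evaluator <- function(trials, window = 13L, step = 3L) {
  force(trials)
  function(feats) {
    tables <- lapply(trials, windowize, selected = feats, window = window,
                     step = step)
    fold_r <- vapply(seq_along(tables), function(i) {
      model <- fit_window_lr(tables[-i])
      predict_window_lr(model, tables[[i]])$r
    }, numeric(1))
    list(score = mean(fold_r), spec = NULL, detail = list(fold_r = fold_r))
  }
}

#' Intrasubject leave-one-out evaluation with forward feature selection
#'
#' Runs the full subject-level procedure for one emotion quality: forward
#' selection over the subject's unmasked features, where each stage's score
#' is the mean of the leave-one-out fold correlations (exhaustive lag
#' search at stage 1 and GA at stages 2--3 for the NARX model; plain
#' refitting for the sliding-window baseline), capped at 3 features for
#' NARX and unlimited for the baseline.
#'
#' @param trials List of [feature_set()] objects (the analysed trials of
#'   one subject and quality).
#' @param model_kind `"narx"` or `"lr"`.
#' @param candidates Candidate features; defaults to the features available
#'   (unmasked) in every trial.
#' @param delta Minimum score improvement per added feature.
#' @param max_k Maximum features (default 3 for NARX, unlimited for LR).
#' @param control,bounds,ga,mode,seed Passed to the NARX machinery.
#' @return A list of class `cv_result`: `subject`, `quality`, `model_kind`,
#'   `trace` (selection trace), `features`, `best_spec`, `fold_r`,
#'   `mean_r`.
#' @export
loocv_evaluate <- function(trials, model_kind = c("narx", "lr"),
                           candidates = NULL, delta = 0.01, max_k = NULL,
                           control = narx_control(n_units = 0),
                           bounds = c(1L, 11L), ga = NULL,
                           mode = "free_run", seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(trials) >= 2)
  if (is.null(candidates)) {
    masks <- vapply(trials, function(tr) tr$mask, logical(13))
    candidates <- narx_feature_names()[rowSums(!masks) == 0]
  }
  max_k <- max_k %||% if (model_kind == "narx") 3 else Inf
  ev <- if (model_kind == "narx") {
    narx_stage_evaluator(trials, control = control, bounds = bounds,
                         ga = ga, mode = mode, seed = seed)
  } else {
    lr_stage_evaluator(trials)
  }
  trace <- forward_feature_selection(candidates, ev, delta = delta,
                                     max_k = max_k)
  final <- trace[nrow(trace), ]
  detail <- attr(trace, "details")[[nrow(trace)]]
  fold_r <- if (model_kind == "narx") {
    spec <- final$spec[[1]]
    loocv_score(trials, spec, control = control, mode = mode,
                seed = seed)$fold_r
  } else {
    detail$fold_r
  }
  structure(
    list(subject = trials[[1]]$subject, quality = trials[[1]]$quality,
         model_kind = model_kind, trace = trace,
         features = final$features[[1]],
         best_spec = final$spec[[1]], fold_r = fold_r,
         mean_r = mean(fold_r)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s %s [%s] features: %s | mean r = %.3f\n",
              x$subject, x$quality, x$model_kind,
              paste(x$features, collapse = " + "), x$mean_r))
  invisible(x)
}

#' Paired Wilcoxon comparison of two models
#'
#' Two-sided Wilcoxon signed-rank test on per-subject best mean
#' correlations, paired by subject.  Zero differences are dropped
#' (Wilcoxon's original treatment); the exact null distribution is used for
#' n up to 25 when there are no ties, otherwise the normal approximation
#' with continuity correction.
#'
#' @param narx_r,lr_r Equal-length numeric vectors paired by subject.
#' @return A tibble with `statistic`, `p_value`, `n`, `n_nonzero` and
#'   `method`.
#' @export
compare_models <- function(narx_r, lr_r) {
  stopifnot(length(narx_r) == length(lr_r))
  n <- length(narx_r)
  if (n < 5) warn("fewer than 5 pairs: the signed-rank test has low power")
  d <- narx_r - lr_r
  nz <- sum(d != 0)
  if (nz == 0) {
    # all pairs identical: no evidence against the null by convention
    return(tibble::tibble(statistic = 0, p_value = 1, n = n, n_nonzero = 0,
                          method = "Wilcoxon signed rank (all differences zero)"))
  }
  v_max <- nz * (nz + 1) / 2
  v_obs <- sum(rank(abs(d[d != 0]))[d[d != 0] > 0])
  if (v_obs %in% c(0, v_max)) {
    # one-signed differences: the sign-flip null gives the exact extreme
    # tail even under ties in |d|
    return(tibble::tibble(statistic = v_obs,
                          p_value = min(1, 2 / 2^nz), n = n, n_nonzero = nz,
                          method = "Wilcoxon signed rank exact (extreme statistic)"))
  }
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(
    stats::wilcox.test(narx_r, lr_r, paired = TRUE, exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = n, n_nonzero = nz, method = wt$method)
}

#' Feature-occurrence ranking across subjects
#'
#' Counts, per quality and model kind, how many subjects carry each feature
#' anywhere in their final optimal feature set (each subject counts once
#' per feature).
#'
#' @param optimal_sets Tibble with columns `quality`, `model_kind`,
#'   `subject` and a list-column `features`, or a list of `cv_result`
#'   objects.
#' @return A tibble `quality`, `model_kind`, `feature`, `count`, sorted by
#'   decreasing count within quality and model kind.
#' @export
rank_features <- function(optimal_sets) {
  if (!is.data.frame(optimal_sets)) {
    optimal_sets <- dplyr::bind_rows(lapply(optimal_sets, function(cv) {
      tibble::tibble(quality = cv$quality, model_kind = cv$model_kind,
                     subject = cv$subject, features = list(cv$features))
    }))
  }
  long <- tidyr::unnest(
    dplyr::mutate(optimal_sets,
                  features = lapply(.data$features, unique)),
    "features"
  )
  out <- dplyr::count(long, .data$quality, .data$model_kind,
                      feature = .data$features, name = "count")
  dplyr::arrange(out, .data$quality, .data$model_kind,
                 dplyr::desc(.data$count), .data$feature)
}

#' Median and median absolute deviation
#'
#' The unscaled MAD: the median of absolute deviations from the median (no
#' consistency constant).
#'
#' @param x Numeric vector (non-empty).
#' @return A tibble with `n`, `median` and `mad`.
#' @export
#' @examples
#' summary_stats(c(1, 2, 3)) # median 2, mad 1
summary_stats <- function(x) {
  if (!length(x)) abort("empty input")
  med <- median(x)
  tibble::tibble(n = length(x), median = med, mad = median(abs(x - med)))
}

#' Apriori frequent-itemset mining over optimal feature sets
#'
#' Level-wise candidate generation with pruning by the Apriori property
#' (every subset of a frequent itemset must itself be frequent).  Support
#' counts subjects whose optimal feature set contains the itemset; the
#' default threshold of 6 subjects and the cap of 3 items match the study
#' conditions (at most 3 features were ever combined).
#'
#' @param transactions List of character vectors (one optimal feature set
#'   per subject).
#' @param min_support Minimum number of containing subjects.
#' @param max_k Largest itemset size considered.
#' @return A tibble `k`, `itemset` (items joined by `+`), `items`
#'   (list-column), `support`, sorted by `k` then decreasing support.
#' @export
apriori_frequent_sets <- function(transactions, min_support = 6,
                                  max_k = 3) {
  transactions <- lapply(transactions, function(tr) sort(unique(tr)))
  support_of <- function(items) {
    sum(vapply(transactions, function(tr) all(items %in% tr), logical(1)))
  }
  items <- sort(unique(unlist(transactions)))
  empty <- tibble::tibble(k = integer(0), itemset = character(0),
                          items = list(), support = integer(0))
  if (!length(items)) return(empty)

  rows <- list()
  sup1 <- vapply(items, function(i) support_of(i), integer(1))
  frequent <- lapply(items[sup1 >= min_support], identity)
  for (i in seq_along(frequent)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = 1L, itemset = frequent[[i]], items = list(frequent[[i]]),
      support = support_of(frequent[[i]]))
  }
  k <- 2L
  while (k <= max_k && length(frequent) > 1) {
    # join step: unite frequent (k-1)-itemsets sharing their first k-2 items
    cand <- list()
    for (a in seq_along(frequent)) {
      for (b in seq_along(frequent)) {
        if (b <= a) next
        u <- sort(union(frequent[[a]], frequent[[b]]))
        if (length(u) == k) cand[[paste(u, collapse = "+")]] <- u
      }
    }
    # prune step: all (k-1)-subsets must be frequent
    freq_keys <- vapply(frequent, paste, character(1), collapse = "+")
    cand <- Filter(function(u) {
      subs <- combn(u, k - 1, paste, collapse = "+")
      all(subs %in% freq_keys)
    }, cand)
    next_frequent <- list()
    for (u in cand) {
      s <- support_of(u)
      if (s >= min_support) {
        next_frequent[[length(next_frequent) + 1]] <- u
        rows[[length(rows) + 1]] <- tibble::tibble(
          k = k, itemset = paste(u, collapse = "+"), items = list(u),
          support = s)
      }
    }
    frequent <- next_frequent
    k <- k + 1L
  }
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$k, dplyr::desc(.data$support), .data$itemset)
}

#' Intersubject evaluation with repeated random subject splits
#'
#' Per repeat, subjects are split 14/7 (roughly 70/30 when fewer than 21
#' subjects are supplied, with a warning); a GA finds the lag structure for
#' the fixed feature set.  Two objective modes are provided and recorded in
#' every result: `"paper"` maximises the mean correlation over the test
#' trials themselves (the study's literal construction, which leaks test
#' information into the search), while `"holdout"` maximises on a
#' validation split of the training subjects and only reports on the
#' untouched test subjects.
#'
#' @param dataset Tibble with columns `subject` and `features` (list of
#'   [feature_set()]), one row per analysed trial, already restricted to
#'   one quality.
#' @param features Character vector (length 1--3) of the feature set used.
#' @param repeats Number of random splits.
#' @param seed Master seed: splits and GA runs derive from it.
#' @param mode Objective mode, see above.
#' @param train_frac Training fraction used when fewer than 21 subjects.
#' @param control,bounds,ga Passed to the NARX machinery.
#' @return A tibble with one row per repeat: `rep`, `mode`, `train`
#'   and `test` (list-columns of subject ids), `n_train_trials`,
#'   `n_test_trials`, `par` (list), `mean_r`.
#' @export
intersubject_evaluate <- function(dataset, features, repeats = 10,
                                  seed = 1L, mode = c("paper", "holdout"),
                                  train_frac = 2 / 3,
                                  control = narx_control(n_units = 0),
                                  bounds = c(1L, 11L), ga = NULL) {
  mode <- match.arg(mode)
  subjects <- sort(unique(dataset$subject))
  ns <- length(subjects)
  n_train <- if (ns >= 21) 14L else {
    warn("fewer than 21 subjects: using a proportional split")
    max(2L, round(train_frac * ns))
  }
  n_par <- 1L + 2L * length(features)
  cfg <- ga %||% ga_config(n_par)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      2 * repeats))
  trials_of <- function(ids) {
    dataset$features[dataset$subject %in% ids]
  }
  score_on <- function(par, fit_ids, eval_ids) {
    spec <- lag_spec_from_par(par, features, bounds = bounds)
    model <- fit_narx(trials_of(fit_ids), spec, control = control)
    mean(vapply(trials_of(eval_ids), function(tr) {
      sim <- simulate_narx(model, tr)
      pearson_r(sim$y_hat, sim$y_true)
    }, numeric(1)))
  }

  purrr::map_dfr(seq_len(repeats), function(r) {
    train <- with_seed(seeds[2 * r - 1], sample(subjects, n_train))
    train <- sort(train)
    test <- setdiff(subjects, train)
    if (mode == "paper") {
      evaluator <- function(par) score_on(par, train, test)
    } else {
      n_val <- max(1L, round(0.3 * n_train))
      val <- with_seed(seeds[2 * r - 1] + 1L, sample(train, n_val))
      fit_ids <- setdiff(train, val)
      evaluator <- function(par) score_on(par, fit_ids, val)
    }
    res <- ga_lag_search(evaluator, n_par, config = cfg, bounds = bounds,
                         seed = seeds[2 * r])
    final_r <- if (mode == "paper") res$score else
      score_on(res$par, train, test)
    n_train_trials <- sum(dataset$subject %in% train)
    n_test_trials <- sum(dataset$subject %in% test)
    tibble::tibble(
      rep = r, mode = mode, train = list(train), test = list(test),
      n_train_trials = n_train_trials, n_test_trials = n_test_trials,
      par = list(res$par), mean_r = final_r
    )
  })
}

#' Meaningful features for the intersubject analysis
#'
#' Features present in at least `min_count` subjects' optimal sets (a
#' quarter of 21 subjects, i.e. 6, by default), capped at 3, excluding any
#' feature masked for at least one subject (this reproduces the exclusion
#' of inspiration time, which could not be computed for 6 participants).
#'
#' @param ranking Output of [rank_features()] filtered to one quality and
#'   model kind.
#' @param min_count Minimum occurrence count.
#' @param exclude Features to drop (masked anywhere).
#' @param max_features Cap on the returned set.
#' @return Character vector of feature names.
#' @export
meaningful_features <- function(ranking, min_count = 6, exclude = character(0),
                                max_features = 3) {
  keep <- ranking[ranking$count >= min_count &
                    !(ranking$feature %in% exclude), ]
  head(keep$feature, max_features)
}
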