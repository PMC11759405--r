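#' Genetic-algorithm configuration for integer lag search
#'
#' Defaults follow standard integer-GA practice: population 50, tournament
#' selection of size 3, uniform crossover with probability 0.8, per-gene
#' random-reset mutation with probability 0.1, and 2 elites.  The maximum
#' generation count follows the 200-per-parameter rule (1000 for 2 features,
#' 1400 for 3); the search also stops when the average absolute change of
#' the best fitness over a 50-generation window falls below `1e-6`.  Under
#' the integer encoding the constraint violation is always zero; it is
#' retained in the generation log for fidelity.
#'
#' @param n_params Number of integer parameters being optimised.
#' @param pop_size Population size.
#' @param p_cross Crossover probability per pair.
#' @param p_mut Per-gene mutation probability.
#' @param elite Number of elites copied unchanged.
#' @param max_generations Generation cap (default `200 * n_params`).
#' @param stall_window,stall_tol Stall window (generations) and tolerance.
#' @param constraint_tol Retained stopping constant (vacuous for integers).
#' @param tournament Tournament size.
#' @return A list of class `ga_config`.
#' @export
#' @examples
#' ga_config(7)$max_generations # 1400
ga_config <- function(n_params, pop_size = 50, p_cross = 0.8, p_mut = 0.1,
                      elite = 2, max_generations = 200L * n_params,
                      stall_window = 50L, stall_tol = 1e-6,
                      constraint_tol = 1e-3, tournament = 3L) {
  stopifnot(n_params >= 1, pop_size >= 4,
            p_cross >= 0, p_cross <= 1, p_mut >= 0, p_mut <= 1,
            elite >= 0, elite < pop_size)
  structure(as.list(environment()), class = "ga_config")
}

# memoising wrapper around an integer-vector evaluator; failures score -Inf
make_cached_evaluator <- function(evaluator) {
  cache <- new.env(parent = emptyenv())
  failures <- new.env(parent = emptyenv())
  eval_one <- function(par) {
    key <- paste(par, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(evaluator(par), error = function(e) {
      failures[[key]] <- conditionMessage(e)
      -Inf
    })
    if (!is.finite(val)) val <- -Inf
    cache[[key]] <- val
    val
  }
  list(eval = eval_one,
       n_evaluated = function() length(ls(cache)),
       failures = function() as.list(failures))
}

#' Exhaustive search over the 3-parameter lag grid
#'
#' For a single exogenous feature only 3 integer parameters (`n_y`, `n_u`,
#' `n_k`) need optimising, so the full grid (1331 points for bounds 1--11)
#' is evaluated.  Ties are broken by the lexicographically smallest
#' `(n_y, n_u, n_k)`; evaluator failures score `-Inf` and are logged.
#'
#' @param evaluator Function taking an integer vector `c(n_y, n_u, n_k)`
#'   and returning a scalar score (larger is better).
#' @param bounds Inclusive integer bounds.
#' @return A list with `par`, `score`, `n_eval` and `failures`.
#' @export
exhaustive_lag_search <- function(evaluator, bounds = c(1L, 11L)) {
  vals <- seq.int(bounds[1], bounds[2])
  grid <- expand.grid(n_k = vals, n_u = vals, n_y = vals)
  grid <- grid[, c("n_y", "n_u", "n_k")]
  # lexicographic order in (n_y, n_u, n_k) so the first maximum is the tie-break
  grid <- grid[order(grid$n_y, grid$n_u, grid$n_k), ]
  ce <- make_cached_evaluator(evaluator)
  gm <- as.matrix(grid)
  scores <- vapply(seq_len(nrow(gm)), function(i) {
    ce$eval(as.integer(gm[i, ]))
  }, numeric(1))
  best <- which.max(scores)
  list(par = as.integer(gm[best, ]), score = scores[best],
       n_eval = nrow(gm), failures = ce$failures())
}

#' Genetic-algorithm search over integer lag parameters
#'
#' Integer chromosomes within the bounds; tournament selection, uniform
#' crossover, random-reset mutation and elitism, fully seeded.  Evaluations
#' are cached, so revisited chromosomes cost nothing.  Stops at the
#' generation cap or when the best fitness stalls (see [ga_config()]).
#' Returns the best-ever individual.
#'
#' @param evaluator Function from an integer parameter vector to a scalar
#'   score (larger is better); failures score `-Inf`.
#' @param n_params Chromosome length (5 for 2 features, 7 for 3).
#' @param config A [ga_config()].
#' @param bounds Inclusive integer bounds per gene.
#' @param seed Integer seed.
#' @return A list with `par`, `score`, `generations` (log tibble with best,
#'   mean, sd of fitness and the vacuous constraint violation), `n_eval`
#'   and `failures`.
#' @export
ga_lag_search <- function(evaluator, n_params,
                          config = ga_config(n_params),
                          bounds = c(1L, 11L), seed = 1L) {
  stopifnot(inherits(config, "ga_config"), config$n_params == n_params)
  ce <- make_cached_evaluator(evaluator)
  vals <- seq.int(bounds[1], bounds[2])
  ps <- config$pop_size

  with_seed(seed, {
    pop <- matrix(sample(vals, ps * n_params, replace = TRUE),
                  nrow = ps, ncol = n_params)
    fit <- apply(pop, 1, ce$eval)
    best_par <- pop[which.max(fit), ]
    best_score <- max(fit)
    best_hist <- best_score
    log_rows <- list()

    for (gen in seq_len(config$max_generations)) {
      # elitism
      ord <- order(fit, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(config$elite)], , drop = FALSE]
      # tournament selection + uniform crossover + random-reset mutation
      while (nrow(new_pop) < ps) {
        pick <- function() {
          cand <- sample.int(ps, config$tournament)
          cand[which.max(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        if (runif(1) < config$p_cross) {
          swap <- runif(n_params) < 0.5
          tmp <- p1[swap]
          p1[swap] <- p2[swap]
          p2[swap] <- tmp
        }
        for (child in list(p1, p2)) {
          mut <- runif(n_params) < config$p_mut
          child[mut] <- sample(vals, sum(mut), replace = TRUE)
          if (nrow(new_pop) < ps) new_pop <- rbind(new_pop, child)
        }
      }
      pop <- new_pop
      fit <- apply(pop, 1, ce$eval)
      if (max(fit) > best_score) {
        best_score <- max(fit)
        best_par <- pop[which.max(fit), ]
      }
      best_hist <- c(best_hist, best_score)
      fin <- fit[is.finite(fit)]
      log_rows[[gen]] <- tibble::tibble(
        generation = gen, best = best_score,
        mean = if (length(fin)) mean(fin) else NA_real_,
        sd = if (length(fin) > 1) sd(fin) else NA_real_,
        constraint_violation = 0
      )
      # stall rule: average absolute change of the best fitness over the window
      if (length(best_hist) > config$stall_window) {
        recent <- tail(best_hist, config$stall_window + 1)
        if (mean(abs(diff(recent))) < config$stall_tol) break
      }
    }

    list(par = as.integer(best_par), score = best_score,
         generations = dplyr::bind_rows(log_rows),
         n_eval = ce$n_evaluated(), failures = ce$failures())
  })
}

#' Sequential forward feature selection
#'
#' Greedy, no backtracking: stage 1 always accepts the single best feature;
#' each later stage accepts the best extension only if its score exceeds the
#' incumbent by at least `delta` (0.01 on the correlation scale).  Stops at
#' `max_k` features, when no extension qualifies, or when the candidates are
#' exhausted.  Score ties are broken by the canonical 13-feature order of
#' [narx_feature_names()].
#'
#' @param candidates Character vector of candidate feature names (a
#'   subject's unmasked features).
#' @param stage_evaluator Function taking a character vector of features and
#'   returning either a scalar score or a list with elements `score` and
#'   (optionally) `spec` and `detail`.
#' @param delta Minimum improvement for accepting an additional feature.
#' @param max_k Maximum number of features (3 for NARX; `Inf` lets the
#'   baseline add features freely).
#' @return A `selection_trace` tibble with one row per accepted stage
#'   (`stage`, `feature_added`, `features` list-column, `score`, `spec`
#'   list-column); attributes `stop_reason` and `details`.
#' @export
forward_feature_selection <- function(candidates, stage_evaluator,
                                      delta = 0.01, max_k = 3) {
  canon <- narx_feature_names()
  # canonical order for the 13 study features; other names keep their order
  candidates <- c(intersect(canon, candidates),
                  setdiff(unique(candidates), canon))
  if (!length(candidates)) abort("empty candidate set")

  normalise <- function(res) {
    if (is.list(res)) {
      list(score = res$score, spec = res$spec %||% NULL,
           detail = res$detail %||% NULL)
    } else {
      list(score = res, spec = NULL, detail = NULL)
    }
  }

  selected <- character(0)
  rows <- list()
  details <- list()
  incumbent <- -Inf
  stop_reason <- "candidates exhausted"

  for (stage in seq_len(min(max_k, length(candidates)))) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) {
      stop_reason <- "candidates exhausted"
      break
    }
    best <- NULL
    best_feature <- NULL
    # canonical iteration order + strict improvement makes ties deterministic
    for (f in remaining) {
      res <- normalise(stage_evaluator(c(selected, f)))
      if (is.null(best) || res$score > best$score) {
        best <- res
        best_feature <- f
      }
    }
    accept <- if (stage == 1) TRUE else best$score >= incumbent + delta
    if (!accept) {
      stop_reason <- sprintf("improvement below %.3g", delta)
      break
    }
    selected <- c(selected, best_feature)
    incumbent <- best$score
    rows[[stage]] <- tibble::tibble(
      stage = stage, feature_added = best_feature,
      features = list(selected), score = best$score,
      spec = list(best$spec)
    )
    details[[stage]] <- best$detail
    if (stage == max_k) stop_reason <- "max features"
  }
  if (!length(rows)) abort("stage evaluator produced no usable score")
  out <- dplyr::bind_rows(rows)
  attr(out, "stop_reason") <- stop_reason
  attr(out, "details") <- details
  class(out) <- c("selection_trace", class(out))
  out
}
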