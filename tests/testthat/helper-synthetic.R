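# small shared builders for the test suite

# one short synthetic subject: reduced protocol, full pipeline
small_subject <- function(seed = 1, trials_per_quality = 3, quality = "Q1",
                          profile = subject_profile()) {
  cfg <- protocol_config(n_subjects = 1, qualities = quality,
                         trials_per_quality = trials_per_quality, seed = seed)
  tl <- generate_protocol(cfg, seed = seed)
  ds <- generate_recording(tl, profile, cfg, seed = seed + 10,
                           subject = "S01")
  list(config = cfg, timeline = tl, dataset = ds)
}

# a plain feature table (no masking machinery) for regressor/window tests
toy_feature_table <- function(n = 60, seed = 42, features = c("u1", "u2")) {
  withr::with_seed(seed, {
    out <- tibble::as_tibble(stats::setNames(
      lapply(features, function(f) stats::rnorm(n)), features))
    out$intensity <- stats::rnorm(n)
    out
  })
}

# naive triple-loop regressor construction used as the independent oracle
naive_regressors <- function(y, U, spec) {
  n <- length(y)
  maxlook <- max(spec$n_y, max(spec$n_k + spec$n_u))
  rows <- list()
  for (t in (maxlook + 1):n) {
    row <- c()
    for (i in seq_len(spec$n_y)) row <- c(row, y[t - i])
    for (j in seq_along(spec$features)) {
      lin <- c()
      for (l in spec$n_k[j]:(spec$n_k[j] + spec$n_u[j])) {
        lin <- c(lin, U[t - l, j])
      }
      row <- c(row, lin, lin^2)
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

# brute-force frequent-itemset enumeration (independent Apriori oracle)
brute_force_itemsets <- function(transactions, min_support, max_k) {
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (k in seq_len(min(max_k, length(items)))) {
    sets <- utils::combn(items, k, simplify = FALSE)
    for (s in sets) {
      supp <- sum(vapply(transactions, function(tr) all(s %in% tr),
                         logical(1)))
      if (supp >= min_support) {
        out[[length(out) + 1]] <- list(items = s, support = supp)
      }
    }
  }
  out
}
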