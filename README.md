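# narxaffect

Continuous emotion-intensity estimation from peripheral physiology with
dynamic NARX wavelet-network models.

## The problem

When people watch emotionally evocative pictures, their subjectively felt
emotion *intensity* changes continuously — and so do autonomic signals:
skin conductance (GSR/EDA), heart rate derived from the pulse wave, and
respiration. `narxaffect` implements a subject-dependent pipeline that
predicts a continuously reported intensity trace from 13 physiological
feature series, using **nonlinear autoregressive exogenous (NARX)
models**: the intensity at time *t* is explained by its own recent past
and by delayed, possibly nonlinear contributions of the physiological
features. Because the fitted lag structure is interpretable (how many
samples of history matter, and how delayed each physiological channel is
relative to feeling), the approach is aimed at affective-computing and
psychophysiology researchers who care about *dynamics*, not just
point classification.

The model output is

y(t) = y₀ + (z(t) − z̄)ᵀ P l + W(z(t)) + S(z(t)),

where the regressor vector z(t) stacks the output lags
y(t−1)…y(t−n_y) and, for each selected feature u_m, the delayed input
lags u_m(t−n_k)…u_m(t−n_k−n_u) together with their squares; P projects
onto the principal axes of the training regressors, l holds the linear
weights, and W and S are sums of dilated/translated radial wavelet and
scaling units. The integer lag structure (n_y, n_u, n_k per feature, each
in 1–11, i.e. 0.39–4.29 s at the 2.56 Hz feature rate) is found by
exhaustive search for one feature and by an integer genetic algorithm for
two or three, inside a sequential forward feature selection that adds a
feature only when the mean leave-one-out correlation improves by at
least 0.01 (at most 3 features). A sliding-window linear regression
(window 13 samples ≈ 5 s, step 3 samples, max/min/mean/sd per window)
serves as the static baseline, and a paired Wilcoxon signed-rank test
compares the two. Feature-occurrence ranking and Apriori frequent-itemset
mining summarise which features matter across subjects.

The study's raw recordings are not publicly deposited, so the package
ships (a) a protocol-faithful synthetic-data generator — 21 subjects × 3
emotion qualities × 8 trials (first per quality is practice), trial
timeline 2 s cue + 3 × 15 s images + 30 s black + 30 s neutral at 256 Hz —
and (b) the published per-participant result tables as plain-text
fixtures, from which all printed summary statistics are recomputed.

## A worked example

Simulate one subject whose intensity is generated by a known NARX process
on two features, run the full selection + lag search, and inspect the
result:

```r
library(narxaffect)

proc <- narx_ground_truth_process(bounds = c(1L, 4L)) # known truth
trials <- simulate_coupled_subject(seed = 3, process = proc)

cv <- loocv_evaluate(
  trials, "narx",
  candidates = c("gsr_filtered", "rsp_rate", "hr_filtered",
                 "expiration_time"),
  max_k = 2, bounds = c(1L, 4L),
  ga = ga_config(5, pop_size = 16, max_generations = 15, stall_window = 8),
  seed = 3
)
cv
#> <cv_result> S01 Q1 [narx] features: rsp_rate + gsr_filtered | mean r = 0.996
cv$best_spec
#> <lag_spec> n_y=2 | rsp_rate(n_u=1, n_k=3), gsr_filtered(n_u=2, n_k=2)
```

Selection recovers exactly the two features that truly drive the
intensity (the generator uses `gsr_filtered` and `rsp_rate` with input
windows starting at lag 2): the delay found for `gsr_filtered` is exact
and the one for `rsp_rate` is within one lag of the true window onset,
and the mean leave-one-out correlation of the free-run prediction is
0.996. The baseline on the same subject:

```r
glance(loocv_evaluate(trials, "lr",
                      candidates = c("gsr_filtered", "rsp_rate",
                                     "hr_filtered")))$mean_r
#> [1] 0.478
```

The static window regression reaches r ≈ 0.48 where the dynamic model
reaches r ≈ 0.99 — the package's desk-scale reproduction of the study's
headline contrast. The published per-participant tables are available as
fixtures:

```r
fx <- load_paper_fixtures()
summary_stats(fixture_best_results(fx$intra, "Q1", "narx")$best_r)
#> # A tibble: 1 × 3
#>       n median   mad
#>   <int>  <dbl> <dbl>
#> 1    21  0.662 0.046
```

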