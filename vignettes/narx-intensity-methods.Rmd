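---
title: "Dynamic emotion-intensity estimation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic emotion-intensity estimation: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(narxaffect)
```

This vignette is the package's own account of its science: the model and
its assumptions, what the synthetic-data generator does and does not
emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made.

## The estimation problem

A subject watches blocks of emotional pictures while three peripheral
signals are recorded — skin conductance (GSR), the pulse wave, and a
respiration belt — and continuously reports felt emotion intensity with a
physical input device. The task is subject-dependent regression of the
continuous intensity trace from physiological *dynamics*: the value now
depends on the recent history of both the report and the body. Each
emotion quality (e.g. joy, regret, fear) is modelled separately; one
model never mixes trials of different qualities, and trials are never
concatenated across their boundaries.

## The NARX wavelet-network model

With intensity $y$ and selected feature series $u_1,\dots,u_m$ (at most
three), the regressor vector at discrete time $t$ is

$$z(t) = \big[\,y(t-1),\dots,y(t-n_y),\;
u_1(t-n_{k1}),\dots,u_1(t-n_{k1}-n_{u1}),\;
u_1(t-n_{k1})^2,\dots,\;\dots\big],$$

i.e. linear output lags, and for each feature a window of $n_u+1$ linear
input terms starting at delay $n_k$, each accompanied by its square
(quadratic input terms capture the nonlinear character of autonomic
responses; output lags stay linear). The prediction is

$$\hat y(t) = y_0 + (z(t)-\bar z)^{\mathsf T} P\, l + W(z(t)) + S(z(t)),$$

with $y_0$ the pooled training-target mean, $P$ the principal axes of
the standardised training regressors (components kept up to a
$1-10^{-6}$ variance fraction, with a guard against numerically null
directions), $l$ ordinary least-squares weights on the projected
regressors, and $W$, $S$ sums of radial wavelet and scaling units.

**Unit shapes.** The nonlinearity operates on a radial combination of
the projected regressors: for a unit with centre $c$ and scalar dilation
$a$, $\rho = a^2\lVert x - c\rVert^2$, with the Mexican-hat-type wavelet
$\psi(\rho) = (d-\rho)e^{-\rho/2}$ ($d$ the projected dimension) and the
Gaussian scaling function $\varphi(\rho) = e^{-\rho/2}$. Candidate
centres are subsampled training points (50 by default, seeded), dilations
are dyadic ($2^0$–$2^3$), and units are added greedily on the linear
fit's residual — each unit's amplitude by one-dimensional least squares —
until 8 units or until the relative residual-variance improvement drops
below $10^{-4}$. In the noise-free linear case the units contribute
essentially nothing and the whole apparatus collapses to ordinary least
squares; a unit test asserts this. During lag search the unit count is
set to zero (pure linear + quadratic regression), which makes the search
orders of magnitude cheaper; the functional form is unchanged because
the quadratic input terms — the part of the nonlinearity that the lag
structure interacts with — are always present.

**Lag conventions.** The input window runs from $n_k$ to $n_k+n_u$
inclusive, i.e. $n_u+1$ linear terms per feature (common
system-identification software uses an "$n_u$ terms" convention instead;
the regressor builder is the single place where the convention lives,
and the brute-force oracle test pins it down). All lag parameters are
integers in $[1, 11]$: at the 2.56 Hz feature rate this spans
0.39–4.29 s. There is no instantaneous ($t-0$) input term — the delay
lower bound of 1 excludes it by construction.

**Evaluation modes.** The default is *free-run* simulation: after an
initial ground-truth warm-up of max-lag samples, the model's own
predictions feed the output lags, so the reported correlation reflects a
genuine generative claim. A *one-step-ahead* mode (all output lags from
ground truth) is available and flagged in the output; on the training
data it reproduces the stored residuals exactly. Free-run recursions can
diverge for unstable fitted structures; a guard aborts beyond
$|\hat y| > 10^3$ and the search scores such structures as $-\infty$,
steering the optimisation toward stable models.

## Search and selection

* **One feature** (3 parameters): exhaustive evaluation of the full
  $11^3 = 1331$ grid; ties break by the lexicographically smallest
  $(n_y, n_u, n_k)$ — an invention needed for determinism.
* **Two/three features** (5/7 parameters): an integer genetic algorithm —
  tournament selection (size 3), uniform crossover (0.8), per-gene
  random-reset mutation (0.1), 2 elites, population 50 — capped at
  200 generations per parameter (1000/1400) and stopped early when the
  mean absolute change of the best fitness over a 50-generation window
  falls below $10^{-6}$. Under the integer encoding the constraint
  violation is identically zero; it is still logged per generation for
  fidelity. Evaluations are memoised, so revisited chromosomes are free.
  The GA internals are not dictated by the method itself; the chosen
  operators are standard integer-GA defaults and all are configurable.
* **Forward selection**: stage 1 always accepts the best single feature;
  each later stage accepts the best extension only if the mean LOOCV
  correlation improves by at least 0.01, up to 3 features (the baseline
  regression may add features without limit). All lag parameters are
  re-optimised jointly at each stage (the alternative — freezing the
  previous stage's lags — is not taken, because features interact).
  Score ties break by a fixed canonical order of the 13 features.

The evaluation score throughout is the mean Pearson correlation over
leave-one-out folds across a subject's 7 analysed trials (6 train,
1 test, every trial tested once). A zero-variance series yields r = 0 by
documented convention, so constant predictions score as uninformative
rather than propagating `NA`.

## The sliding-window baseline

The comparator is a deliberately *static* model on identical inputs:
windows of 13 samples (≈ 5 s) advancing by 3 samples (≈ 1 s); per window
and feature the max, min, mean and population standard deviation are
predictors and the window-mean intensity is the target. The baseline
never sees per-sample intensity — the window table type enforces this.
Its correlation is computed on the window-level series (whether the
original construction re-expanded predictions to sample level is not
determinable; window level is implemented and flagged here). Larger
windows would denoise the baseline but also destroy the dynamics being
compared, so the window length is held at the dynamic model's time
scale.

## Statistics over subjects

Per-subject best mean correlations are summarised by the median and the
*unscaled* median absolute deviation (no 1.4826 consistency constant).
NARX and baseline are compared by a two-sided paired Wilcoxon signed-rank
test: zero differences are dropped; the exact null is used for up to 25
non-zero pairs without ties; with one-signed differences the exact
sign-flip tail $2/2^{n}$ is reported even under ties in $|d|$ (the
textbook exact routine refuses ties, but the extreme tail is
distribution-free). Feature relevance is the occurrence count of each
feature in subjects' final optimal sets (once per subject), and common
combinations are mined with a level-wise Apriori (support = number of
subjects whose optimal set contains the itemset, threshold 6 ≈ a quarter
of 21 subjects, itemsets up to size 3 because selection never combines
more). An exhaustive enumeration oracle cross-checks the miner in the
tests.

## Intersubject analysis

Ten repeats of a random 14/7 subject split (98/49 trials with full
data); the feature set is fixed to the features appearing in at least 6
subjects' optimal sets (capped at 3, excluding any feature that is
masked for at least one subject — this reproduces the exclusion of
inspiration time, which cannot be computed for some participants), and
the GA optimises the lag structure. Two objective modes are implemented
and recorded in every result row: the *paper-literal* mode maximises the
mean correlation over the 49 test trials themselves — the construction
the original analysis describes, which leaks test information into the
search — and a *leakage-free* mode that optimises on a validation split
of the training subjects and reports on the untouched test subjects.
The leaky mode is the default for comparability; the flag in the output
is the honesty mechanism.

## The synthetic-data generator

No raw recordings are deposited, so every downstream stage is exercised
on synthetic data generated under the study's protocol: 21 subjects,
3 qualities × 8 trials (first per quality practice and excluded),
trial = 2 s cue + 3 × 15 s images + 30 s black + 30 s neutral = 107 s,
24 trials ≈ 43 min, acquisition at 256 Hz so that decimation by 100
yields exactly 2.56 Hz. Channel models:

* **GSR** — tonic level + slow drift + stimulus-locked bi-exponential
  skin-conductance responses (rise 0.75 s, decay 2.5 s; peak amplitude
  proportional to the image's nominal intensity level) + white noise.
* **Pulse** — a peaked periodic waveform $e^{3(\cos\phi - 1)}$ whose
  instantaneous rate is resting HR + a latency-shifted stimulus gain +
  slow spontaneous heart-rate variability (AR(1), correlation time 8 s,
  sd 2 bpm).
* **Respiration** — a sinusoid whose rate and depth are modulated by the
  stimulus, the rate carrying its own spontaneous variability
  (sd 1 breath/min).
* **Intensity** — a first-order-lagged (τ = 2 s), reaction-delayed
  (0.5 s) knob response to the nominal image level, clipped to [0, 1]
  (the physical device's numeric range is unknowable; any affine
  rescaling is invisible to a correlation cost, so [0, 1] is safe).

Nominal image levels default to a per-trial permutation of
{0.3, 0.6, 0.9} so every trial contains intensity variation. The
spontaneous cardiac and respiratory variability is essential, not
decorative: without it all features are deterministic functions of the
single stimulus drive and hence so collinear that one feature suffices
for prediction, which would make multi-feature selection untestable.
What the generator does *not* emulate: picture content and semantics,
habituation across images, motion artefacts, sensor drift or detachment,
and between-channel physiological coupling beyond the shared stimulus
drive. Consequently, passing tests demonstrate that the pipeline
recovers known structure under realistic noise and protocol timing — not
that real physiology satisfies the model.

For parameter-recovery experiments the package defines a canonical
ground-truth process (`narx_ground_truth_process()`): intensity generated
by a stable NARX recursion on the filtered GSR and the respiration rate
($n_y = 2$, input windows of three lags starting at delay 2 for both
features, equal material coefficients at every covered lag, innovation
sd 0.3, output min-max scaled per trial). The equal-coefficient window
is deliberate: a NARX delay is only identifiable up to the *onset* of
the input window (a window starting earlier but covering the true lags
fits equally well at realistic sample sizes), so a recovery benchmark
must pin the onset by making every covered lag carry signal — then any
competing window reaching the same fit has its onset within one lag of
the truth. Coefficients are balanced against the natural scales of the
two features (GSR sd ≈ 0.1 µS, respiration-rate sd ≈ 1.4 breaths/min) so
both contribute materially and neither dominates selection.

## Feature extraction details

The 13 features are computed at the raw rate and then decimated by 100.
Decimation keeps the last sample of each 100-sample block (so every
retained value has a full block of raw data behind it; a 105 s trimmed
trial yields 268 samples), after a zero-phase anti-alias Butterworth
low-pass at 80 % of the new Nyquist. Heart rate comes from
prominence-thresholded pulse peaks (0.3 × inter-quartile range, 0.3 s
refractory period), inter-beat intervals outside 30–200 bpm or deviating
more than 30 % from the running median are rejected and bridged, and the
beat-to-beat rates are linearly interpolated onto the uniform time base.
Breath cycles are alternating trough/peak/trough triplets from
prominence-thresholded extrema with a minimum cycle length of 1.5 s;
cycle-level features (rate, inspiration/expiration time,
inhalation/exhalation depth) are expanded by sample-and-hold from each
cycle's end. Fewer than three usable beats or cycles masks the
corresponding features; masked features are excluded from that subject's
candidate set and never imputed. A flat respiration channel therefore
masks all seven respiration-derived features.

The *running rate* — the proprietary toolbox feature of the original
acquisition software — is implemented as a documented surrogate: the
mean over a 5 s evaluation window ending now, minus the mean over a 10 s
reference window ending 5 s earlier, divided by the reference magnitude
(+10⁻⁶); the warm-up region is zero. The window lengths are knobs, not a
claim of equivalence to the proprietary definition.

Filtering follows amplifier-style defaults: GSR/pulse get a 4th-order
Butterworth low-pass at 30 Hz plus a 50 Hz biquad notch (Q = 30);
respiration gets a 0.1–30 Hz band-pass (2nd-order high-pass cascaded
with the low-pass, which keeps the very low corner well conditioned)
plus the notch. Everything is applied forward–backward (zero phase) with
odd-reflection padding sized to each filter's settling time — 2 s for
the 30 Hz/notch stages, 10 s for the 0.1 Hz high-pass, 30 × factor
samples for the anti-alias stage; shorter pads leave measurable edge
transients, which the module tests caught. The first 2 s of every trial
are discarded *before* feature extraction (participants were adjusting
the device then); the trim is guarded by a flag so it cannot be applied
twice. The pipeline order is: filter → trim → extract features at the
raw rate → decimate features to 2.56 Hz.

## Problem sizes used in the shipped experiments

The tests and the acceptance script run the full procedure at desk
scale, chosen once as the smallest sizes at which each scientific claim
is meaningful: parameter recovery uses 10 replicate subjects, 4
candidate features, lag bounds [1, 4] (containing the true lags) and a
reduced GA (population 16, ≤ 15 generations); the population comparison
uses 15 subjects, 3 candidates, bounds [1, 3], at most 2 features per
model and a further reduced GA. The fixture-table statistics involve no
randomness and reproduce the published medians, MADs, occurrence counts
and the Apriori outcome exactly. Full-scale settings (bounds [1, 11],
population 50, 13 candidates, 3 features) are the defaults of the
exported functions.

## Known limitations

* The wavelet-network estimator reproduces the published functional form,
  but the original study's exact estimator is undocumented; greedy unit
  selection with dyadic dilations is one reasonable member of that
  family.
* Free-run versus one-step evaluation is not specified in the original
  description; free-run is the default here as the stronger claim, and
  both are available.
* The intersubject paper-literal objective is optimistically biased by
  construction; use the leakage-free mode for honest generalisation
  estimates.
* Min–max scaling of the generated intensity is per trial, which
  introduces a trial-specific affine distortion relative to the raw
  generating recursion; correlations are invariant to it within a trial,
  but pooled fits across trials see slightly heterogeneous targets —
  matching the calibration drift a physical reporting device would show.
* At 2.56 Hz, delays beyond 4.29 s (11 lags) are not representable;
  slower autonomic responses alias into the autoregressive part.
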