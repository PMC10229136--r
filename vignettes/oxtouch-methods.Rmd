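---
title: "Methods: simulating and analyzing oxytocin effects on affective touch with fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing oxytocin effects on affective touch with fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtouch)
```

## The analysis problem

Randomized oxytocin administration studies of affective touch ask whether
exogenous oxytocin — given intranasally or orally — changes how pleasant
slow, gentle stroking touch (the stimulus class carried by C-tactile
afferents) feels, and whether that change is visible in cortical
hemodynamics and explicable by the rise in circulating oxytocin.
The designs this package targets have three arms (intranasal oxytocin,
oral oxytocin, placebo), two touch conditions delivered in separate
block-design sessions (gentle stroking touch; medium pressure massage),
prefrontal/temporal fNIRS coverage, blood sampling around the session,
behavioral ratings, and autonomic recordings.

`oxtouch` implements the full computational chain for such a study —
and, crucially, a synthetic cohort generator with the same statistical
structure, so every stage is testable end to end without any recordings.

## Synthetic cohorts

`simulate_cohort()` builds an enrolled roster (default 180 subjects:
analyzed arms of 56/57/58 plus 5 procedure-incomplete and 4
technical-loss exclusions, so the accounting 180 − 5 − 4 = 171 is itself
testable) and, per subject:

* **fNIRS forward model** (`simulate_subject_fnirs()`): per region of
  interest (ROI), the neural drive of each condition is a 30 s boxcar;
  past block offset the drive decays as `exp(-t/tau)` with a
  group-specific prolongation constant `tau`. The drive is convolved
  with the canonical double-gamma HRF (normalized to unit area so a
  sustained response plateaus at the configured amplitude, i.e. betas are
  in µM), scaled by the (ROI, condition) amplitude, and summed with
  per-sample Gaussian noise, sinusoidal physiological components
  (cardiac 1.1 Hz, respiratory 0.25 Hz, Mayer 0.10 Hz; random phase per
  channel) and optional motion artifacts (single-sample spikes and
  baseline steps — exactly the two artifact classes derivative-domain
  repair targets). Default amplitudes make gentle touch drive
  mOFC/mlOFC (0.6 µM) and pSTS (0.5 µM) most strongly and massage drive
  S1 (0.6 µM); oxytocin arms get `tau = 8 s` in mOFC/mlOFC/pSTS for
  gentle touch while placebo gets 0 — the "prolonged response" pattern
  the classifier is meant to detect. Between-subject variability enters
  as a ±20 % multiplicative amplitude jitter and ±2 s additive tau
  jitter.
* **Mediation structure**: the post-treatment plasma change is
  `M = a·X + e_M` and gentle-touch pleasantness is
  `Y = y0 + c'·X + b·M + e_Y`, with `X` a 0/1 indicator of one oxytocin
  route versus placebo. Defaults are the per-route paths `a = 6.57`
  (intranasal) / `2.41` (oral) pg/ml, `b = 0.06` rating points per
  pg/ml, `c' = 0.37` / `0.50`. Error scales (`sigma_m = 8` pg/ml,
  `sigma_y = 1` rating point, placebo baseline 5.5) were chosen once as
  realistic for plasma immunoassay spread and 9-point ratings, and so
  that scale clamping at 1/9 is rare enough (≪1 %) not to bias path
  recovery. Ratings are stored continuously; real instruments are
  discrete, which the generator deliberately does not emulate.
* **Autonomic traces**: RR intervals with sinusoidal low- and
  high-frequency modulation plus white jitter (`simulate_rr()`), and
  skin-conductance traces with a fast-rise/slow-decay phasic kernel at
  block onsets (`simulate_scr()`).

A master seed spawns per-subject substreams through a fixed rule
(`subject_seed(master, index)`), so enlarging a cohort never perturbs
existing subjects, and every generator restores the caller's RNG state.

What passing tests on these cohorts shows — and does not show: the
generator reproduces the *statistical skeleton* the analysis assumes
(group structure, effect topography, mediation paths, spectral content),
not real scalp optics, real motion physics, discrete rating behavior, or
real inter-regional correlation structure. Calibration results below are
statements about the pipeline's correctness, not about any real dataset.

## Preprocessing

Stage order is fixed: optical conversion → polynomial detrend → motion
repair → bandpass.

* **Optical conversion**: `intensity_to_od()` takes
  `OD(t) = −log(I(t)/mean(I))`; `mbll()` solves the two-wavelength
  extinction system `dOD = E · dc · DPF · d` in least-squares form.
  The extinction table (Gratzer/Cope compilation, 760/850 nm, in
  cm⁻¹ mM⁻¹) and the differential pathlength factor (6.0 at both
  wavelengths) are shipped as overridable constants since acquisition
  hardware manuals, not analyses, fix them. `forward_mbll()` is the
  exact inverse used for round-trip testing.
* **Detrend**: least-squares polynomial per channel, default order 1 —
  drift in these recordings is dominantly linear, and the order is
  configurable for curvier drifts.
* **Motion repair** (`tddr()`): temporal derivative distribution repair —
  below a 0.5 Hz split the derivative is iteratively reweighted with
  Tukey's biweight (tuning 4.685) on robustly centered/scaled residuals
  until the weighted mean converges (machine precision or 50
  iterations), re-integrated, and the high-frequency component restored.
  Two numerical notes. First, at 6.78 Hz a *single-sample* spike lies
  mostly above the 0.5 Hz split and therefore largely survives the
  conventional variant; motion transients of roughly 2 s and longer are
  repaired almost completely. `split_freq = NULL` reweights the
  full-band derivative and removes sub-second spikes too, at the cost of
  also touching cardiac-band signal (which this pipeline discards at the
  next stage anyway). Second, the biweight systematically down-weights
  even clean derivative samples by a few percent, so repeated
  application keeps shrinking in-band noise slightly; "idempotent in
  practice" holds when artifacts dominate the derivative outliers, which
  is the intended operating regime.
* **Bandpass**: order-4 Butterworth, 0.01–0.08 Hz, applied
  forward–backward (`filtfilt`) for zero phase; effective attenuation is
  doubled. With the lower edge at 0.0030 of Nyquist the recursion's
  poles sit very close to the unit circle: outputs are accurate to about
  1e-3 relative (verified in the test suite as the scale at which
  superposition holds), which is far below any quantity the pipeline
  consumes.

## First-level GLM and ROI statistics

`build_design()` convolves the four condition boxcars (massage, touch,
rest-after-massage, rest-after-touch) with the canonical HRF and appends
an intercept; `fit_glm()` is per-channel OLS with rank checking;
`contrast_stim_minus_rest()` takes the stimulation-minus-matched-rest
beta difference; `roi_aggregate()` averages member channels (mOFC =
12–15, mlOFC = 10/11/16/17, lOFC = 9/18, pSTS = 1–4/23–26, S1 =
5–8/19–22).

The canonical HRF is a double gamma with mode exactly at 6 s, undershoot
mode at 16 s, 1:6 undershoot ratio, truncated at 32 s; the kernel is
peak-normalized (a documentation contract) and area-normalized inside
the design builder (so a sustained response of amplitude A yields
β = A). Because rest is modeled explicitly, the four convolved
regressors plus intercept are *nearly* collinear (stimulation and rest
boxcars tile the session, so their convolved sum approaches a
constant): the system remains full-rank through onset/offset transients,
noiseless recovery is exact, but beta variances are inflated relative to
an implicit-baseline parameterization. This mirrors the modeled design
faithfully and is the reason contrasts, not single betas, are the
reported quantities. No prewhitening is applied; after a 0.01–0.08 Hz
prefilter the residual spectrum is already dominated by the passband,
and this is documented as a limitation rather than corrected.

## Group classification

Features are the block-averaged oxy-Hb time courses 5–35 s after gentle
touch onset (203 samples at 6.78 Hz), averaged within mOFC, mlOFC and
pSTS and concatenated in that fixed order (609 values). Curves are
*concatenated*, not pooled, so regional shape differences survive; no
pre-window baseline subtraction is applied by default (the bandpass
already centers the signal; an onset-anchored subtraction flag exists).

`loo_classify()` predicts each held-out subject's arm by Pearson
correlation (cosine by option) with each arm's mean feature vector,
the subject's own arm mean computed without them. Exact similarity ties
and undefined similarities (constant features) count as errors and are
tallied — a conservative tie rule. `permutation_test()` rebuilds the
null by reshuffling arm labels (default 10 000 draws) and reports the
literal proportion of null accuracies ≥ the observed one; the
`(b+1)/(m+1)` estimator is available but off by default, matching the
plain-proportion convention. The implementation reduces each
permutation to O(n²) work on a precomputed Gram matrix, which is what
makes the 200-replicate calibration suites and the 50-replicate
end-to-end suite affordable.

## Autonomic indices

Event-locked skin-conductance amplitude is the mean over onsets of
`max(window) − value(window start)`, floored at 0 per event, in a 15 s
window — "base" is defined as the window-start sample, one of several
defensible readings, and documented as such. Heart rate is
`60000/mean(RR)`. HF power integrates the one-sided periodogram of the
4 Hz cubic-spline tachogram (linearly detrended) over 0.15–0.40 Hz, in
ms². DFA α1 fits `log F(n)` against `log n` over box sizes 4–16 beats on
the integrated, mean-centered series with per-box linear detrending —
the conventional short-term HRV scaling range. Expected anchors: ~0.5
for white RR noise, ~1.0 for 1/f surrogates, < 0.5 for anti-correlated
series.

## Inference layer

One-way and mixed (split-plot) repeated-measures ANOVAs are classical
balanced decompositions (`aov` with subject error strata) reporting F,
df, p and partial η²; with one between factor (3 arms) and a two-level
within factor at N = 171 the treatment effect has df (2, 168), and with
condition × region (2 × 5) within factors the region-stratum effects
have df (4, 672)/(8, 672). No sphericity correction is applied by
default — two-level factors need none and the five-level region factor
is reported uncorrected, with a Greenhouse–Geisser option deliberately
out of scope. Bonferroni adjustment is the literal `min(1, m·p)`.

`mediate()` fits the three OLS regressions (`M~X`, `Y~X+M`, `Y~X`),
reports `a`, `b`, `c`, `c'` and the indirect effect `a·b` (the identity
`c = c' + a·b` holds to numerical precision), and bootstraps the
indirect effect by resampling subjects (default 5000 draws) with
percentile 2.5/97.5 bounds — matching the bracketed-interval reporting
convention; bias-corrected intervals are intentionally not the default.
Calibration note: percentile intervals for a *product* are conservative
at the joint null (`a = b = 0` makes the interval straddle zero almost
always), so null-fidelity is checked one-sidedly, while two-sided
±3-point coverage calibration is tested at the default generating paths.

`anova_sample_size()` finds the smallest total N, stepped in multiples
of k for equal arms, whose noncentral-F power (ncp = f²·N, df
(k−1, N−k)) reaches the target; at k = 3, f = 0.25, α = 0.05, power
0.80 this gives 159 (53 per arm). Unconstrained allocation would admit
158; equal-arm stepping is the planning convention this solver follows.

## Problem sizes used by the test suite

The calibration suites run 200 replicates each (chance-level
classification at 50 + 50 subjects; permutation-p uniformity at 10 + 10;
mediation coverage and path recovery at 56 + 58 with 1000 bootstrap
draws), and the end-to-end discrimination suite runs 50 replicate
two-arm cohorts of 16 + 16 subjects, gentle-touch session only,
artifact-free, with 1000 permutations — sizes chosen so the full suite
stays in the minutes range on one core while keeping Monte-Carlo error
well inside the tested tolerances.

## Known limitations

* No short-separation regression, wavelet/spline motion correction, or
  HbR-based analyses (HbR is produced by the conversion stage but not
  consumed downstream).
* The recording interchange format is the plain-text channel × sample
  CSV written by `write_recording_csv()`; binary container formats are
  not read or written.
* The generator's physiological components are stationary sinusoids;
  real cardiac/respiratory dynamics are amplitude- and
  frequency-modulated.
* Mediation assumes a single continuous mediator and OLS paths; no
  multiple-mediator or Bayesian variants.
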