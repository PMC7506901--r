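---
title: "Decoding motor imagery: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micsp)
```

## The decoding problem

Imagining a limb movement suppresses the power of the sensorimotor mu
(8–12 Hz) and beta (18–26 Hz) rhythms over the contralateral motor cortex
(event-related desynchronization, ERD). A two-class motor-imagery
brain–computer interface therefore reduces to a statistical problem:
given epoched multichannel EEG trials, find spatial and spectral
projections in which the two classes differ in variance, select the few
informative features, and classify. This vignette explains how `micsp`
models each stage, which knobs matter, and what the shipped tests do and
do not establish.

## Preprocessing

Trials are band-pass filtered to 8–30 Hz with a Butterworth filter of
overall order 6 (an order-3 low/high prototype; `signal::butter(3, ...)`),
covering both sensorimotor rhythms while rejecting drift and line noise.
Two phase modes are exposed because the literature rarely states which is
used: the default `zero_phase` applies the filter forward and backward
(squaring the magnitude response and cancelling group delay, so features
stay aligned with the epoching window), and `causal` is available for
online-faithful simulation. Epoching windows are half-open in samples,
`[round(t_start·fs), round(t_start·fs) + K)` with
`K = round((t_end − t_start)·fs)`, with 0 s at the task cue — typical
windows are 0.5–3.5 s at 100 Hz and 0.5–2.5 s at 250/256 Hz.

## CSP

Class covariances average the per-trial `DDᵀ/trace(DDᵀ)`; trace
normalization makes trials commensurable regardless of their absolute
power. The Rayleigh problem `max wᵀC̄₁w / wᵀC̄₂w` is solved as a
symmetric-definite generalized eigenproblem by whitening `C̄₂` rather than
forming `C̄₂⁻¹C̄₁`: the whitened problem is symmetric, so eigenvectors are
exactly `C̄₂`-orthogonal in floating point, which the test suite asserts to
1e-8. A ridge `1e-10 · trace(C̄₂)/C` guards the inversion; eigenvector
signs are fixed by making each filter's largest-magnitude coefficient
positive (signs are mathematically arbitrary but matter for
reproducibility); filters are scaled so `wᵀC̄₂w = 1`. The first and last
`m = 3` eigenvectors are kept — `m` is configurable but 3 is the
convention this implementation follows, giving 6 virtual channels.

Variance in the log-variance features uses the population divisor `1/K`;
the normalized ratio `var(Z_p)/Σvar(Zᵢ)` is insensitive to the choice,
which is why the identity `Σ_p exp(f_p) = 1` holds either way and is
asserted to 1e-10.

## Sub-band feature extraction

Three extractors operate on the projected channels:

* **DWT features.** A db4 discrete wavelet transform of depth `L` splits
  `(0, fs/2]` into `A_L, D_L, …, D_1`. Depth defaults to 3 for
  `fs ≤ 128` and 4 above, so that terminal bands are a few Hz wide —
  coarser resolutions cannot isolate the mu band, finer ones chase noise.
  250 Hz and 256 Hz are planned identically. Energy and sample standard
  deviation (`n − 1` divisor) of each selected band's coefficients are the
  features, channel-major, energy before spread.
* **WPD features.** The full packet tree splits every branch, giving `2^L`
  equal bands. Terminal nodes come out of the recursion in Paley order;
  the high/low outputs of every split at an odd frequency position are
  swapped so that intervals can be assigned in natural frequency order —
  omitting this reordering silently mislabels bands, which the tone
  localization test would catch.
* **Filter-bank features.** Ten overlapping order-6 Butterworth bands
  (8–12, 10–14, …, 26–30 Hz) and the log population variance per band and
  channel, band-major.

Sub-band *selection* defaults to "interval intersects 8–30 Hz". This rule
makes the selected interval set identical across adjacent decomposition
depths (3 vs 4 at 100 Hz, 4 vs 5 at 250 Hz), a consistency the test suite
asserts; a stricter fully-within rule and explicit index lists are
provided because the intersect rule keeps a band reaching up to 50 Hz at
100 Hz sampling, and users may reasonably prefer to drop it.

Boundary handling defaults to periodization, which keeps db4 orthonormal
so sub-band energies sum exactly to signal energy (Parseval, asserted to
1e-8 on lengths divisible by `2^L`; odd lengths are padded by repeating
the last sample and conservation becomes approximate). Half-point
symmetric extension is available when wrap-around artifacts are a concern.
Sub-band intervals use ideal dyadic edges; real db4 filters leak across
them, so tests assert energy *localization* thresholds, never exact
containment.

## Sparse selection

Features are column-standardized (train statistics, applied frozen to
test) so one λ grid is comparable across extractors whose features differ
in scale by orders of magnitude. Weights regress the ±1 labels:

* LASSO: `½‖y − Xw‖² + λ‖w‖₁`, solved by ISTA with step `1/‖XᵀX‖₂`
  (the spectral norm is computed by power iteration to 1e-10).
* LOG: `½‖y − Xw‖² + λ Σᵢ log(1 + |wᵢ|/a)` with `a = 0.001`, solved by
  iterative log thresholding.

The log penalty is treated as a separable sum, the form consistent with
an element-wise shrinkage operator; a non-separable variant
(`λ log(1 + ‖w‖₁/a)`) is recorded on the fitted object for transparency
but not optimized. Two shrinkage modes exist deliberately. The closed
form (`paper_prox`, the default)
`sign(v)/2·(|v| − a + sqrt((a−|v|)² + 4·max(a|v| − λ/γ, 0)))`
returns 0 only when `|v| ≤ a` with the clamp active, and `≈ v − a·sign(v)`
otherwise; the exact proximal map (`exact_prox`) compares the admissible
root of the stationarity quadratic with 0 and may jump to 0 where the
closed form does not. `exact_prox` enjoys a monotone-descent guarantee
(asserted per-step to 1e-12) and is pinned to a brute-force scalar
minimizer; `paper_prox` is the reproduction default. With `a ≥ 1e4` the
exact map collapses to soft thresholding — the analytic bridge between the
two penalties — which is also tested.

Stopping is by relative iterate change below 1e-6 or 1000 iterations;
non-convergence is reported on the object, not thrown. λ is selected from
`2^{−5}, 2^{−4.8}, …, 2^{5}` (51 values) by 10-fold CV, stratified by
class under a recorded seed, scoring held-out accuracy of a Fisher
discriminant on the surviving features (empty supports score 0); ties go
to the larger, sparser λ. Scoring by squared error is available. Both the
scoring rule and the standardization are conventions of this
implementation — the upstream literature leaves them unstated.

## Secondary selection and classification

For each threshold `τ ∈ {0, 0.1, …, 0.8}` the features with `|wᵢ| > τ`
(raw weights by default; a max-normalized mode is available since the
scale of the grid is a convention) train one Fisher discriminant:
direction `(S_w + ridge·I)⁻¹(μ₊ − μ₋)` with pooled within-class scatter,
ridge `1e-8·trace(S_w)/P`, midpoint bias, boundary ties to +1. Subsets
are nested and shrink with τ.

The published evaluation takes the *maximum* per-threshold test accuracy
(empty subsets scoring 0). That rule consults test labels to pick the
model, so it is an optimistic protocol; it is reproduced faithfully as
the default, and a label-blind alternative — inner-CV threshold choice on
training data only — ships alongside (`evaluation_rule = "cv"`). On
separable synthetic data the two agree to within 0.05 on average; under
the null the max rule inflates accuracy by a few points, which is visible
in the acceptance numbers.

## The synthetic generator

`generate_epochs()` draws band-limited Gaussian sources, scales a
designated mu-band source's variance by `variance_ratio` for class +1
trials, mixes sources into channels through a random orthonormal-column
matrix, and adds white sensor noise. Filtered white noise is rescaled by
the band-pass filter's analytic white-noise power gain (numerical
integral of `|H|⁴` for the zero-phase filter), so expected per-trial
covariances equal `A·diag(v)·Aᵀ + σ²I` — asserted against Monte-Carlo
averages — while trial-to-trial power still fluctuates naturally.

Defaults: 250 Hz, 2 s trials, 12 channels, 12 sources — one ERD mu source
(baseline variance 0.2), one beta source (0.5), ten broadband 8–30 Hz
background sources (1.0), sensor noise SD 0.1, variance ratio 4. The
background sources matter: because CSP trace-normalizes, generalized
eigenvalues are rescaled by the ratio of class traces, so the planted
ratio is recoverable from the top eigenvalue only when the ERD source is
a small share (here ≈ 2%) of total band power. That is also the
physiologically sensible regime — the mu rhythm is a modest fraction of
broadband EEG power. Mixing is drawn from the config seed and trial noise
from a (seed, session) pair, so two "sessions" share a forward model but
not noise, mirroring session-wise train/test splits.

What the generator does *not* emulate: eye blinks and muscle artifacts,
line noise, nonstationarity across a session, volume-conduction
correlation structure between sources, and 1/f background spectra.
Passing tests therefore demonstrate correctness of the algorithms under
the linear-mixing ERD model, not robustness on recorded EEG.

## Problem sizes and numerical choices

The test and acceptance runs use compact configurations chosen to keep
the statistical claims meaningful: eigenvalue recovery uses 200 trials of
the default 12-channel setting; end-to-end accuracy uses 40 train and 40
test trials per class over 10 seeds at sensor-noise SD 0.05 ("high SNR")
and 10 seeds with `variance_ratio = 1` (exchangeable classes, where mean
accuracy must sit in the chance band 0.35–0.65). Degenerate inputs are
first-class: all-zero trials, zero-variance projected channels, empty
feature subsets, single-class fits and malformed feature headers all
raise classed errors (or score 0 where the protocol says so) rather than
propagating NaNs.

## Known limitations

* The max-accuracy evaluation is optimistically biased by construction;
  use the CV rule for honest generalization estimates.
* `paper_prox` descent is not guaranteed monotone for the non-convex
  penalty (only `exact_prox` is); in practice it converges on
  well-conditioned problems, which is asserted over seeds.
* Wavelet sub-band intervals are ideal dyadic edges; db4 leakage blurs
  them, so narrow ERD effects near band boundaries can split across
  features.
* EDF/GDF readers are not included; continuous data enter through
  `raw_recording()` or the text epoch container.
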