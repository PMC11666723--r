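---
title: "Methods: multimodal uncertainty-adjustment analysis with maatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal uncertainty-adjustment analysis with maatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maatkit)
```

## The scientific problem

In a cued multi-attribute attention task, a compound stimulus carries four
binary features (color, motion direction, size, saturation). Before each
eight-trial block, a cue announces which 1–4 features may be probed; the
number of cued candidates is the *target load*, an experimental dial on
decision uncertainty. The question the analysis chain answers is how the
brain — and, in a two-group design, how an older brain differently —
adjusts decision, excitability and arousal systems as load rises:
drift rates fall, frontal theta power and pupil dilation rate rise,
posterior alpha falls, sample entropy rises, and the aperiodic 1/f slope
of the EEG spectrum shallows. `maatkit` implements that chain end to end
on synthetic data with planted effects, so every extraction stage can be
validated against a known ground truth.

## The drift-diffusion decision model

Choices and response times are modeled as a Wiener diffusion with unit
diffusion coefficient between absorbing bounds `0` and `a` (boundary
separation), start point `w·a` fixed at `w = 0.5` (accuracy coding),
drift `v` toward the correct bound and a non-decision shift `t0`.
The first-passage density is evaluated by the standard small-time /
large-time series split, with the truncation order chosen from the
analytic error bound at a series tolerance of `1e-10`. Two closed forms
anchor the tests: the absorption probability at the correct bound,
`(1 − e^{−va}) / (1 − e^{−2va})` for `w = 1/2`, and the mean decision
time `(a/2v)·tanh(va/2)`.

Fitting maximizes the 5% outlier mixture likelihood
`(1 − p)·f_wiener + p·uniform[0.25 s, max RT]` per subject, after
excluding premature responses (< 250 ms). Five nested variants share or
free `v`, `a`, `t0` across load conditions; AIC/BIC replace the deviance
information criterion because hierarchical MCMC is substituted by
per-subject maximum likelihood — the group priors in the original
hierarchical approach are a regularization device, and the acceptance
standard here is parameter recovery, not posterior reproduction.

Numerical choices worth knowing:

* The simulator uses Euler steps with a Brownian-bridge correction for
  within-step bound crossings (`exp(−2·d₁·d₂/dt)`), so the default
  `dt = 1 ms` already matches the analytic density to a
  Kolmogorov–Smirnov distance below 0.01 at `n = 10^5`.
* With an outlier mixture, RTs below `t0` are legitimately explained by
  the uniform component, so the optimizer caps `t0` at the RT median
  rather than the minimum RT. (Capping at the minimum drags `t0` down
  whenever an outlier lands near 0.25 s and biases `v` and `a`
  upward — measurably so.)
* Starting values come from EZ-diffusion moment inversion; optimization
  is box-constrained L-BFGS-B with bounds `v ∈ [−8, 8]`,
  `a ∈ [0.3, 5]` — implementation constants, since boundary separation
  is deliberately unconstrained scientifically.

## EEG signatures

* **Time-frequency power** uses 7-cycle complex Morlet wavelets
  (2–15 Hz for theta/alpha, 8–25 Hz for mu-beta), 50 ms output steps,
  with `log10` applied at the single-trial level before averaging.
  Edge samples within 3.5 Gaussian SDs of an epoch boundary are flagged.
* **Centro-parietal ramp (CPP)**: response-locked epochs are low-pass
  filtered at 8 Hz, trial-averaged per condition, and summarized by the
  OLS slope over −250..−100 ms and the mean amplitude within ±50 ms of
  the response (threshold proxy). Slopes are fit on condition averages,
  matching the reported analysis granularity; per-trial fitting exists
  but is off by default.
* **Mu-beta**: 8–25 Hz power remapped to contra/ipsilateral given each
  trial's response side, baseline-corrected per condition, slope over
  −250..−50 ms.
* **SSVEP**: sliding 1 s Hann-tapered FFTs (100 ms steps); the 30 Hz
  estimate is normalized by subtracting the plain mean of the 28 and
  32 Hz sidebands (the source phrase "Hanning-based multitaper" is
  internally ambiguous — a Hann window is not a Slepian taper — so a
  single Hann taper is used), then a −700..−100 ms temporal baseline is
  removed.
* **Time-resolved sample entropy** (`m = 2`, `r = 0.5`): window samples
  are pooled across trials as *discontinuous segments* — templates
  never span a trial boundary, but template pairs may come from
  different trials. `r` is a fraction of the pooled SD of all samples
  entering one window estimate, recomputed per window; this implicitly
  variance-normalizes each time bin, so no temporal baseline is
  applied. An 8–15 Hz band-stop removes the alpha rhythm first.
  Matching uses Chebyshev distance `≤ r`; `B = 0` or zero-variance
  windows are flagged undefined, never zeroed. The compiled counter is
  certified by exact integer agreement with an independent O(N²)
  brute-force matcher.
* **Aperiodic (1/f) slope**: PSDs (2–80 Hz, 0.5 Hz spacing,
  Hann-tapered, zero-padded to 20 s) are fit iteratively in log-log
  space: fit a line, flag strongly positive residuals as oscillatory
  peaks (≥ 2 residual SDs *and* ≥ 0.05 log₁₀ units, the latter so
  numerically exact power laws do not flag rounding wiggles), refit on
  non-peak points until stable. The exponent is minus the log-log
  slope.
* **Filters**: no IIR filter design package is available in the target
  environment, so all "6th-order zero-phase Butterworth" operations are
  implemented in the frequency domain with the squared Butterworth
  magnitude response — identical magnitude to forward-backward IIR
  filtering and exactly zero phase (a symmetric input stays symmetric,
  which is a package test). Mirror padding softens edge wrap-around.

## Pupillometry

Samples inside blink annotations, or where the z-scored first
derivative of the *vertical gaze* channel (the default screening
channel; the pupil channel is a config option) exceeds 3 SDs, are
flagged with a 150 ms pad on both sides and linearly interpolated;
edge gaps stay missing because interpolation never extrapolates. Trials
over 50% flagged are rejected with a reason. The arousal signature is
the first difference scaled to units/s computed at the native rate,
anti-alias decimated to 100 Hz, and smoothed with a 300 ms moving
median; differencing *before* decimation minimizes aliasing of spike
remnants. Missingness propagates through the smoothing window — a
window containing any missing sample is missing, because silent
zero-filling would bias load slopes.

## Pseudo-trial bootstrap decoding

For each left-out trial and each of 100 bootstrap repeats, the
remaining trials of each class are randomly partitioned into three
folds and fold-averaged into pseudo-trials; two pseudo-trials per class
(the excluded third rotates across repeats) train a linear classifier
applied to the left-out trial; per-trial accuracy is the fraction of
correct repeats, independently per time point. Two design choices
matter:

* "Two pseudo-trials per class" enter as training *samples* (a
  4-sample training set), not concatenated along the feature axis —
  feature-axis concatenation would break dimensionality.
* With 4 training samples the solver is immaterial; the classifier is
  the ridge-regularized discriminant in its high-regularization limit
  (class-mean difference, midpoint bias). The contract the tests
  enforce is the decoding *scheme*: separable classes decode at ≥ 99%,
  permuted labels at 50%, pseudo-trial averaging never loses to
  single-trial training.

A calibration subtlety: excluding only the left-out trial leaves its
class averaging one fewer trial than the other, which inflates its
class-mean variance and biases nearest-mean classification measurably
*below* chance. The implementation therefore also excludes one random
opposite-class trial per left-out trial, restoring exact symmetry; null
data then decode at 50% within Monte-Carlo error. By construction the
left-out trial never contributes to any pseudo-trial (a package test
plants an extreme-valued trial and verifies its own accuracy stays at
chance).

## Partial least squares

Task PLS decomposes the group-wise condition-mean matrix (optionally
group-mean-removed, highlighting condition and condition-by-group
effects) by SVD into latent variables `U S V'`; behavioral PLS
decomposes the within-group stacked correlation matrix between a
behavior block and a neural block. Brainscores project each
subject-condition row onto `V`. Inference:

* **Permutation**: condition labels permuted within subject (task) or
  behavior rows shuffled within group (behavioral, preserving neural
  structure); latent variables correspond by singular-value rank;
  `p` is the exceedance fraction over (default) 1000 permutations.
* **Bootstrap ratios**: subjects resampled with replacement,
  stratified within group; each resampled `V` is aligned to the
  original by orthogonal Procrustes rotation (without alignment, sign
  flips inflate the SE); `BSR = V / SE_boot`, thresholded at ±3
  (≈ 99.9% normal interval). Degenerate resamples are redrawn and
  counted.
* **Sign convention**: the largest-magnitude element of each `V`
  column is positive — a deterministic fix of SVD sign indeterminacy.

## Group statistics

First-level linear uncertainty effects are per-subject OLS slopes of a
signature on load (1–4 treated as numeric); groups are compared with
two-sided t-tests. Outliers beyond 3 scaled MADs (1.4826 × median
absolute deviation) are winsorized by clipping to the bound — a
deterministic, order-free rule. Within-subject centering removes each
subject's cross-condition mean and restores the group mean, preserving
condition means exactly. The cluster permutation test forms same-sign
suprathreshold clusters (entry `p < .05` two-sided) under channel
adjacency plus temporal contiguity, requires spatial clusters to span
at least 3 neighboring channels, and compares summed-t masses against a
sign-flip null of maximal masses (significance `p < .025`). The
random-intercept model delegates to `lme4`, drops a non-significant
load × age interaction and refits, and reports normal-approximation
p-values (no Satterthwaite machinery is available in the target
environment); non-convergence falls back to the two-stage path.

## The synthetic world: what it emulates and what it does not

The generators state one world and keep it. A session is 4 runs × 8
blocks × 8 trials (256 trials); each set size appears exactly twice per
run (the source description "every set size once per run" is
arithmetically inconsistent with 8 blocks per run, so twice is used);
no two consecutive blocks share a set size; every cued feature is
probed at least once per block with remaining probe slots round-robin;
the 16 dominant-option combinations are exactly balanced per session.
Cue-set *membership* is sampled uniformly among subsets of the drawn
size — how the original design balanced membership is unstated, so this
is flagged rather than guessed. Stimuli are abstract element-attribute
tables (evidence fractions 60/80/65/60%, coherence 0.2), not pixels;
luminance is constant across loads by construction.

Planted effects (young / old load slopes per unit load above 1):
drift −0.35 / −0.12 on a 2.2 / 1.6 intercept; theta amplitude
+25% / +8%; posterior alpha −20% / −6%; aperiodic exponent −0.15 /
−0.04 from 1.8; high-frequency broadband (the entropy carrier)
+25% / +8%; centro-parietal ramp slope −20% / −7%; pupil dilation rate
+30% / +10%. These magnitudes are chosen once as values a cognitive
neuroscientist would call a clear but realistic modulation, large
enough that a desk-scale cohort recovers their sign reliably; they were
not tuned against test outcomes. One generator-level design fix was
made when the stated world failed its own plant-recovery invariant:
the entropy carrier is band-limited above 85 Hz, because a full-band
carrier floods the 2–80 Hz aperiodic fit range and masks the planted
exponent shift. This mirrors the empirical coupling between broadband
irregularity and the 1/f slope rather than contradicting it.

What a green test does *not* establish: the synthetic EEG has no
artifacts, volume conduction, or inter-subject montage variability;
BOLD patterns are Gaussian with planted class information rather than
hemodynamically convolved time series (the GLM module is exercised on
its own synthetic series); behavioral and neural noise are independent
across modalities except where planted. Green means the *extraction
machinery* is faithful, not that the biology is simulated.

## Pipeline and reproducibility

`run_pipeline()` executes synth → features → DDM fits → decoding → PLS
→ group stats, refuses to run stages whose upstream stage is toggled
off, and writes tables, a log, and a summary JSON embedding provenance
(config hash, seed, package version). All randomness descends from one
session seed through labeled child streams (`split_seed`), so reruns
are byte-identical. Heavy intermediate arrays are regenerated
deterministically from config + seed rather than round-tripped through
bulk text files; the epoched-signal container serializes to a JSON +
TSV text bundle because no HDF5 binding is available in the target
environment. The default cohort is deliberately desk-scale (6 + 6
subjects, signal modalities on one run of 32 trials); the canonical
256-trial session is used for behavior and can be enabled throughout
via `pipeline_config()`.

## Known limitations

* No autoregressive noise modeling in the GLM (OLS only); planted-
  effect recovery is unaffected on white-noise synthetics, which is
  what the acceptance standard measures.
* Mixed-model p-values are Wald-normal approximations.
* Multitaper SSVEP estimation and per-trial CPP slopes exist only as
  configuration options, not defaults.
* The entropy implementation is single-scale; no coarse-graining.
* Hierarchical (shrinkage) DDM estimation is out of scope by design;
  subjects with very few trials per condition will fit noisily and the
  minimum-trial guard refuses clearly underdetermined fits.
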