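# maatkit

Simulation and analysis toolkit for cued multi-attribute perceptual
decision experiments in which the number of cued candidate features
("target load", 1–4) manipulates decision uncertainty.

**Who it is for.** Cognitive neuroscientists who want a tested,
reusable implementation of the full multimodal uncertainty-adjustment
analysis chain — drift-diffusion modeling of choices, EEG decision and
excitability signatures, pupillometric arousal signatures, pseudo-trial
bootstrap decoding of BOLD patterns, and task/behavioral partial least
squares with permutation and bootstrap-ratio inference — together with
a synthetic-data generator that plants known group × load effects, so
every stage can be validated against ground truth without any data
download.

## The models at the core

*Decision model.* Choices/RTs follow a Wiener diffusion with unit
diffusion between bounds 0 and *a*, start *a/2*, drift *v* toward the
correct bound and non-decision time *t₀*. The first-passage density
(small-time/large-time series) enters a 5% outlier-mixture likelihood

&nbsp;&nbsp;&nbsp;&nbsp;L = (1 − p)·f(rt | v, a, t₀) + p·Uniform[0.25 s, max RT],

maximized per subject after excluding RT < 250 ms, with nested variants
(full / drift / drift+threshold / drift+NDT / null) compared by AIC/BIC.

*EEG signatures.* 7-cycle Morlet power (theta/alpha, mu-beta),
centro-parietal ramp slope (−250..−100 ms pre-response) and threshold
(±50 ms), 30 Hz SSVEP with 28/32 Hz sideband normalization,
time-resolved sample entropy (m = 2, r = 0.5 × pooled SD, discontinuous
segments pooled across trials, 8–15 Hz notch), and the aperiodic 1/f
exponent from an iterative peak-excluding log-log fit over 2–80 Hz.

*Multivariate statistics.* Task PLS (SVD of group-mean-removed
condition means, `U S V'`), behavioral PLS (SVD of within-group
brain–behavior correlations), permutation p per latent variable,
Procrustes-aligned bootstrap ratios thresholded at |BSR| ≥ 3,
brainscores = data · V; cluster-based sign-flip permutation tests
(entry p < .05, min 3 neighboring channels, cluster p < .025); MAD
winsorization; within-subject centering; random-intercept load × age
models via lme4.

## Worked example

```r
library(maatkit)

# a two-group synthetic cohort with planted old-group dampening
summary <- run_pipeline(pipeline_config(seed = 42), out_dir = "run1")
summary$signatures$drift[c("young_beta", "old_beta")]
#> $young_beta
#> [1] -0.3661
#> $old_beta
#> [1] -0.129
```

Per-subject drift rates fall by ≈ 0.37 per load step in the young group
but only ≈ 0.13 in the old group — the planted "old-group dampening"
(generator slopes −0.35 vs −0.12), recovered by the full chain:
simulated choices → exclusion rules → mixture-likelihood DDM fits →
per-subject load slopes → group contrast. The same summary reports the
other signatures, e.g. theta power (`young_beta = 0.161`,
`old_beta = 0.063`), posterior alpha (−0.264 vs −0.057), the aperiodic
exponent (−0.153 vs −0.034, against planted −0.15 / −0.04), and the
task-PLS permutation p for the theta load effect (0 of 200 exceedances).

Individual stages are plain functions:

```r
d    <- generate_session_design(seed = 1)        # 256 trials, 32 blocks
beh  <- simulate_behavior(d, effect_config(), "young", seed = 1)
fit  <- fit_ddm(beh[, c("load", "rt", "correct")], variant = "full")
fit$params                                        # v, a, t0 per load
```

A CLI wrapper lives at `inst/cli/maat`
(`maat run-all --config cfg.yaml --seed 3 --out run_dir`).

## Layout

- `R/` — modules: `task_synth`, `ddm`, `eeg_features`, `pupil`,
  `decoding`, `pls`, `group_stats`, `bold_glm`, `pipeline`, I/O.
- `src/` — compiled first-passage density/simulator and the sample-
  entropy match counter.
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (the acceptance criteria).
- `vignettes/uncertainty-multimodal-methods.Rmd` — the methods
  vignette: model assumptions, parameter choices, numerical decisions,
  what the synthetic world does and does not emulate.
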