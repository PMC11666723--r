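Package: maatkit
Title: Multimodal Analysis of Uncertainty Adjustment in a Multi-Attribute
    Attention Task
Version: 0.1.0
Authors@R:
    person("MAAT", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for cued multi-attribute
    perceptual decision experiments in which the number of cued candidate
    features ("target load") manipulates uncertainty. Generates balanced
    session designs and synthetic multimodal recordings (drift-diffusion
    choices and response times, oscillatory and aperiodic EEG-like epochs,
    pupil traces, BOLD-like voxel patterns) with configurable planted
    effects; fits drift-diffusion models by maximum likelihood with an
    outlier mixture and nested model comparison; extracts decision and
    excitability signatures (centro-parietal ramp slope and threshold,
    contralateral mu-beta, wavelet theta/alpha power, steady-state visual
    evoked potentials, time-resolved sample entropy, aperiodic 1/f slope);
    preprocesses pupillometry and computes first-derivative arousal
    signatures; performs pseudo-trial bootstrap linear decoding; runs task
    and behavioral partial least squares with permutation and bootstrap-
    ratio inference; and provides the group-level utilities (linear load
    slopes, MAD winsorization, within-subject centering, cluster-based
    permutation tests, random-intercept models) needed to compare planted
    young/old uncertainty modulation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
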