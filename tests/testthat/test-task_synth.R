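test_that("session designs satisfy every balance invariant across seeds", {
  for (seed in c(1, 7, 99)) {
    d <- generate_session_design(seed = seed)
    expect_equal(nrow(d), 256)
    expect_equal(max(d$block_global), 32)
    expect_true(validate_design(d))
    # adjacent blocks never share a set size, also across run boundaries
    sizes <- tapply(d$load, d$block_global, unique)
    expect_false(any(diff(sizes) == 0))
    # each set size exactly twice per run
    first_of_block <- d[!duplicated(d$block_global), ]
    tab <- table(first_of_block$run, first_of_block$load)
    expect_true(all(tab == 2))
    # 16 dominant-option combinations exactly balanced
    key <- do.call(paste0, d[paste0("dom_", c("color", "direction",
                                              "size", "saturation"))])
    expect_equal(unname(sort(unique(table(key)))), 16)
    expect_equal(length(unique(key)), 16)
  }
})

test_that("probe coverage holds in the minimal one-block session", {
  d <- generate_session_design(n_runs = 1, blocks_per_run = 1,
                               trials_per_block = 4, seed = 3,
                               set_sizes = 4)
  expect_equal(nrow(d), 4)
  expect_equal(sort(d$probe_feature),
               sort(c("color", "direction", "size", "saturation")))
})

test_that("infeasible geometries raise constraint errors naming the invariant", {
  expect_error(generate_session_design(n_runs = 1, blocks_per_run = 1,
                                       trials_per_block = 3, seed = 1,
                                       set_sizes = 4),
               "probe coverage")
  expect_error(generate_session_design(n_runs = 1, blocks_per_run = 2,
                                       trials_per_block = 8, seed = 1,
                                       set_sizes = c(2, 2)),
               "sequencing")
  expect_error(generate_session_design(seed = 1, n_runs = 0), "n_runs")
})

test_that("design generation is a pure function of its seed", {
  d1 <- generate_session_design(seed = 11)
  d2 <- generate_session_design(seed = 11)
  d3 <- generate_session_design(seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1$cue_set, d3$cue_set))
})

test_that("stimulus evidence matches configured ratios and coherence", {
  cfg <- stimulus_config()
  ev <- generate_stimulus_evidence(config = cfg, n_frames = 120, seed = 5)
  n <- length(ev$color)
  se <- 3 / (2 * sqrt(n)) # 3 binomial SEs at p ~ 0.5
  expect_lt(abs(mean(ev$color) - 0.60), se)
  expect_lt(abs(mean(ev$direction) - 0.80), se)
  expect_lt(abs(mean(ev$size) - 0.65), se)
  expect_lt(abs(mean(ev$saturation) - 0.60), se)
  expect_lt(abs(mean(ev$coherent) - 0.20), se)
  # symmetric null at 0.5
  cfg5 <- stimulus_config(evidence = c(color = 0.5, direction = 0.5,
                                       size = 0.5, saturation = 0.5))
  ev5 <- generate_stimulus_evidence(config = cfg5, n_frames = 120,
                                    seed = 6)
  expect_lt(abs(mean(ev5$color) - 0.5), se)
  expect_identical(
    generate_stimulus_evidence(config = cfg, n_frames = 10, seed = 2),
    generate_stimulus_evidence(config = cfg, n_frames = 10, seed = 2))
})

test_that("simulated behavior honors the group/load parameter map", {
  # negative drift slope over load => accuracy decreases monotonically
  # (Monte-Carlo oracle; ~10^4 trials, small-sample noise allowance)
  d <- generate_session_design(n_runs = 40, seed = 2)
  beh <- do.call(rbind, lapply(1:4, function(r)
    simulate_behavior(d, effect_config(), "young", seed = 20 + r)))
  expect_equal(nrow(beh), 4 * nrow(d))
  acc <- tapply(beh$correct, beh$load, mean)
  expect_true(all(diff(acc) < 0.005))
  expect_lt(unname(coef(lm(as.numeric(acc) ~ I(1:4)))[2]), -0.01)
  expect_true(all(beh$rt > 0))
  expect_true(all(beh$excluded == (beh$rt < 0.25)))
  # null case: identical parameters across loads => no load effect
  eff0 <- effect_config(ddm = list(
    young = list(v0 = 1.5, v_slope = 0, a0 = 2, a_slope = 0,
                 t00 = 0.3, t0_slope = 0)))
  beh0 <- simulate_behavior(d, eff0, "young", seed = 22)
  acc0 <- tapply(beh0$correct, beh0$load, mean)
  sl <- coef(lm(as.numeric(acc0) ~ I(1:4)))[2]
  expect_lt(abs(sl), 0.02)
  # determinism
  expect_identical(simulate_behavior(d, effect_config(), "young",
                                     seed = 21),
                   simulate_behavior(d, effect_config(), "young",
                                     seed = 21))
  # missing parameter cell
  expect_error(simulate_behavior(d, effect_config(), "middle", seed = 1),
               "group")
})

test_that("planted aperiodic exponents are recovered from simulated EEG", {
  # chi 2.0 at load 1 down to 1.5 at load 4; oscillations silenced so the
  # exponent is probed in isolation (generation parameters as oracle)
  eff <- effect_config(eeg = list(chi0 = 2, chi_slope = list(young = -1 / 6,
                                                             old = 0),
                                  broadband_sd = 0, theta_amp = 0,
                                  alpha_amp = 0, ssvep_amp = 0))
  d <- generate_session_design(n_runs = 1, seed = 4)
  eeg <- simulate_eeg(d, eff, "young", seed = 31)
  loads <- d$load
  ex <- vapply(c(1, 4), function(ld) {
    sub <- maat_epochs(eeg$stim$data[, , loads == ld, drop = FALSE],
                       eeg$stim$srate, eeg$stim$time, "stimulus",
                       eeg$stim$channels)
    ps <- psd_hann(sub, time_window = c(0.5, 3),
                   channels = c("Pz", "POz", "Oz"))
    sel <- ps$freqs >= 2 & ps$freqs <= 80
    aperiodic_fit(ps$freqs[sel], ps$psd[sel])$exponent
  }, numeric(1))
  expect_lt(abs(ex[1] - 2.0), 0.15)
  expect_lt(abs(ex[2] - 1.5), 0.15)
})

test_that("planted response-locked ramp slopes are recovered", {
  eff <- effect_config(eeg = list(noise_sd = 0.2, cpp_k = list(young = 8,
                                                               old = 5),
                                  cpp_slope = list(young = -0.2,
                                                   old = -0.07)))
  d <- generate_session_design(n_runs = 1, seed = 4)
  eeg <- simulate_eeg(d, eff, "young", seed = 32)
  ks <- vapply(1:4, function(ld) {
    cpp_slope(eeg$resp, trials = which(d$load == ld))$slope
  }, numeric(1))
  planted <- 8 * (1 - 0.2 * (0:3))
  expect_true(all(diff(ks) < 0)) # ordered as planted
  expect_lt(max(abs(ks - planted) / planted), 0.25)
})

test_that("pupil and BOLD generators honor their contracts", {
  d <- generate_session_design(n_runs = 1, seed = 4)
  d8 <- d[d$block_global <= 2, ]
  class(d8) <- class(d); for (a in c("n_runs", "blocks_per_run",
                                     "trials_per_block"))
    attr(d8, a) <- attr(d, a)
  eff_nb <- effect_config(pupil = list(blink_rate = 0))
  pp <- simulate_pupil(d8, eff_nb, "young", srate = 100, seed = 41)
  expect_equal(nrow(pp$blinks), 0)
  expect_identical(pp, simulate_pupil(d8, eff_nb, "young", srate = 100,
                                      seed = 41))
  bd <- simulate_bold(d8, effect_config(), n_voxels = 60, seed = 42)
  expect_equal(dim(bd$patterns), c(nrow(d8), 60, 12))
  expect_equal(dim(bd$betas), c(60, 4))
  expect_identical(bd$betas,
                   simulate_bold(d8, effect_config(), n_voxels = 60,
                                 seed = 42)$betas)
})

test_that("zero-noise rank-1 BOLD plant is recovered exactly by task PLS", {
  d <- generate_session_design(n_runs = 1, seed = 4)
  eff <- effect_config(bold = list(noise_sd = 1e-8))
  # two "subjects" drawn with the same seed share the planted pattern
  subs <- lapply(1:2, function(i)
    simulate_bold(d, eff, n_voxels = 60, seed = 100))
  X <- rbind(t(subs[[1]]$betas), t(subs[[2]]$betas))
  s1 <- task_pls(X, rep(c("s1", "s2"), each = 4),
                 condition = rep(1:4, 2), remove_group_means = FALSE)
  v <- s1$V[, 1]; pl <- subs[[1]]$latent_pattern
  cosine <- abs(sum(v * pl)) / sqrt(sum(v^2) * sum(pl^2))
  expect_gt(cosine, 0.999)
})
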