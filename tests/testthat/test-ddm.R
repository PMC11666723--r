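# Closed-form oracles for the symmetric-start diffusion (unit diffusion):
# P(correct) = (1 - exp(-v*a)) / (1 - exp(-2*v*a)) for start w = 1/2,
# written via z = a/2: (1 - e^{-2vz}) / (1 - e^{-2va});
# E[T_decision] = (a / 2v) * tanh(v * a / 2).
absorb_p <- function(v, a) (1 - exp(-v * a)) / (1 - exp(-2 * v * a))
mean_dt <- function(v, a) (a / (2 * v)) * tanh(v * a / 2)

test_that("simulator matches the closed-form absorption oracles", {
  p <- ddm_params(v = 1, a = 2, t0 = 0, p_outlier = 0)
  s <- simulate_ddm_trials(p, 2e4, seed = 7)
  expect_equal(mean(s$correct), absorb_p(1, 2), tolerance = 0.01)
  expect_equal(mean(s$rt), mean_dt(1, 2), tolerance = 0.02)
  # frozen closed-form values
  expect_equal(absorb_p(1, 2), 0.8807971, tolerance = 1e-6)
  expect_equal(mean_dt(1, 2), 0.7615942, tolerance = 1e-6)
  # symmetric random walk at v = 0 (oracle limit: 1/2)
  p0 <- ddm_params(v = 1e-9, a = 2, t0 = 0, p_outlier = 0)
  s0 <- simulate_ddm_trials(p0, 1e4, seed = 8)
  expect_equal(mean(s0$correct), 0.5, tolerance = 0.02)
  # determinism and contract warnings
  expect_identical(simulate_ddm_trials(p, 100, seed = 3),
                   simulate_ddm_trials(p, 100, seed = 3))
  expect_warning(simulate_ddm_trials(p, 10, seed = 3, dt = 5e-3), "dt")
})

test_that("first-passage density is normalized and matches the oracle mass", {
  for (pars in list(c(1, 2, 0.3), c(0.5, 1.5, 0.2), c(2.5, 1, 0.1))) {
    p <- ddm_params(v = pars[1], a = pars[2], t0 = pars[3])
    tt <- seq(pars[3] + 1e-4, 30, length.out = 5000)
    expect_true(all(first_passage_density(tt, p, "correct") >= 0))
    ic <- integrate(function(t) first_passage_density(t, p, "correct"),
                    pars[3], Inf, rel.tol = 1e-8)$value
    ie <- integrate(function(t) first_passage_density(t, p, "error"),
                    pars[3], Inf, rel.tol = 1e-8)$value
    expect_equal(ic + ie, 1, tolerance = 1e-4)
    expect_equal(ic, absorb_p(pars[1], pars[2]), tolerance = 1e-6)
  }
  expect_equal(first_passage_density(0.1, ddm_params(1, 2, 0.3)), 0)
  expect_error(first_passage_density(1, ddm_params(1, 2, 0.3, load = 1)[
    c("v", "a")]), "class|inherits|params")
})

test_that("simulator and density agree in distribution (KS)", {
  # scaled-down cousin of the n = 1e5 acceptance check
  p <- ddm_params(v = 1.2, a = 1.8, t0 = 0.25, p_outlier = 0)
  s <- simulate_ddm_trials(p, 2e4, seed = 13)
  grid <- seq(p$t0 + 1e-4, 12, length.out = 4000)
  pdf_c <- first_passage_density(grid, p, "correct")
  cdf_c <- cumsum(pdf_c) * diff(grid)[1]
  pc <- cdf_c[length(cdf_c)]
  rr <- sort(s$rt[s$correct == 1])
  theo <- approx(grid, cdf_c / pc, xout = rr, rule = 2)$y
  ks <- max(abs(theo - seq_along(rr) / length(rr)))
  expect_lt(ks, 0.015)
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  v_true <- c(1.5, 1.0); a_true <- 2; t0_true <- 0.3
  trials <- do.call(rbind, lapply(1:2, function(i) {
    s <- simulate_ddm_trials(ddm_params(v_true[i], a_true, t0_true),
                             1000, seed = 40 + i)
    data.frame(load = i, rt = s$rt, correct = s$correct)
  }))
  fit <- fit_ddm(trials, variant = "full")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$v - v_true)), 0.2)
  expect_lt(max(abs(fit$params$a - a_true)), 0.2)
  expect_lt(max(abs(fit$params$t0 - t0_true)), 0.03)
})

test_that("premature responses are excluded and do not affect the fit", {
  s <- simulate_ddm_trials(ddm_params(1.2, 2, 0.3), 400, seed = 50)
  clean <- data.frame(load = 1, rt = s$rt, correct = s$correct)
  fast <- data.frame(load = 1, rt = rep(0.1, 30),
                     correct = rep(1L, 30))
  f1 <- fit_ddm(clean, variant = "full")
  f2 <- fit_ddm(rbind(clean, fast), variant = "full")
  expect_equal(f1$params, f2$params, tolerance = 1e-8)
  expect_equal(f2$n_excluded, 30)
})

test_that("nested variants obey likelihood ordering and model comparison", {
  v_true <- c(1.8, 0.9)
  trials <- do.call(rbind, lapply(1:2, function(i) {
    s <- simulate_ddm_trials(ddm_params(v_true[i], 2, 0.3), 400,
                             seed = 60 + i)
    data.frame(load = i, rt = s$rt, correct = s$correct)
  }))
  fits <- lapply(c("full", "drift", "null"), function(v)
    fit_ddm(trials, variant = v))
  lls <- vapply(fits, function(f) f$logLik, numeric(1))
  expect_true(lls[3] <= lls[1] + 1e-6) # null <= full (nested)
  expect_true(lls[2] <= lls[1] + 1e-6)
  cmp <- compare_models(fits)
  # drift-only generating process: drift variant beats null decisively
  expect_lt(cmp$aic[cmp$variant == "drift"],
            cmp$aic[cmp$variant == "null"])
  # mismatched trial sets refuse comparison
  other <- fit_ddm(trials[trials$rt < 2, ], variant = "null")
  expect_error(compare_models(list(fits[[1]], other)), "identical")
})

test_that("estimated drift is monotone in true drift (recovery grid)", {
  grid <- c(0.5, 1, 1.5, 2, 2.5)
  vh <- vapply(seq_along(grid), function(i) {
    s <- simulate_ddm_trials(ddm_params(grid[i], 1.8, 0.3), 800,
                             seed = 70 + i)
    f <- fit_ddm(data.frame(load = 1, rt = s$rt, correct = s$correct),
                 variant = "full")
    f$params$v
  }, numeric(1))
  expect_equal(cor(vh, grid, method = "spearman"), 1)
  expect_lt(max(abs(vh - grid)), 0.35)      # per-point sampling noise
  expect_lt(abs(mean(vh - grid)), 0.1)      # bias bound
})
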