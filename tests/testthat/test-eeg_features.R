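test_that("wavelet power localizes frequency and scales quadratically", {
  ep <- make_epochs(function(tt, c, tr) sin(2 * pi * 10 * tt),
                    n_ch = 2, n_trials = 2, t_lim = c(-1, 2))
  sp <- morlet_power(ep, freqs = 2:15, log10_transform = FALSE)
  mid <- which.min(abs(sp$time - 0.5))
  for (c in 1:2) {
    expect_equal(sp$freqs[which.max(sp$power[c, , mid])], 10)
  }
  # amplitude doubled -> pre-log power x4 (quadratic power)
  ep2 <- make_epochs(function(tt, c, tr) 2 * sin(2 * pi * 10 * tt),
                     n_ch = 2, n_trials = 2, t_lim = c(-1, 2))
  sp2 <- morlet_power(ep2, freqs = 2:15, log10_transform = FALSE)
  expect_equal(sp2$power[1, 9, mid] / sp$power[1, 9, mid], 4,
               tolerance = 1e-6)
  # log flag recorded and applied
  spl <- morlet_power(ep, freqs = c(10), log10_transform = TRUE)
  expect_true(spl$log10)
  expect_equal(10^spl$power[1, 1, mid], sp$power[1, 9, mid],
               tolerance = 1e-6)
})

test_that("wavelet ridge follows a chirp within 1 Hz", {
  # instantaneous frequency 6 -> 14 Hz over the epoch (construction oracle)
  f0 <- 6; f1 <- 14; t0 <- -1; t1 <- 2
  ep <- make_epochs(function(tt, c, tr) {
    k <- (f1 - f0) / (t1 - t0)
    sin(2 * pi * (f0 * (tt - t0) + k * (tt - t0)^2 / 2))
  }, n_ch = 1, n_trials = 1, t_lim = c(t0, t1))
  sp <- morlet_power(ep, freqs = seq(2, 18, 0.5),
                     log10_transform = FALSE)
  for (tc in c(0.0, 0.5, 1.0, 1.5)) {
    ti <- which.min(abs(sp$time - tc))
    f_inst <- f0 + (f1 - f0) / (t1 - t0) * (tc - t0)
    ridge <- sp$freqs[which.max(sp$power[1, , ti])]
    expect_lt(abs(ridge - f_inst), 1)
  }
})

test_that("wavelet power grows with signal variance (Parseval sanity)", {
  tot <- vapply(c(0.5, 1, 2), function(sdv) {
    set.seed(9)
    ep <- make_epochs(function(tt, c, tr) rnorm(length(tt), 0, sdv),
                      n_ch = 1, n_trials = 3, t_lim = c(-1, 2))
    sp <- morlet_power(ep, freqs = 2:15, log10_transform = FALSE)
    sum(sp$power)
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("ramp slope and threshold extraction are exact on noiseless traces", {
  k <- 7.5
  ep <- make_epochs(function(tt, c, tr) k * tt, n_ch = 4, n_trials = 3,
                    t_lim = c(-0.8, 0.2), channels = c("CPz", "Pz",
                                                       "POz", "Oz"),
                    alignment = "response")
  res <- cpp_slope(ep)
  expect_equal(res$slope, k, tolerance = 0.02)
  expect_equal(res$threshold, 0, tolerance = 0.05)
  flat <- make_epochs(function(tt, c, tr) 3.2, n_ch = 4, n_trials = 3,
                      t_lim = c(-0.8, 0.2),
                      channels = c("CPz", "Pz", "POz", "Oz"),
                      alignment = "response")
  resf <- cpp_slope(flat)
  expect_equal(resf$slope, 0, tolerance = 1e-6)
  expect_equal(resf$threshold, 3.2, tolerance = 1e-6)
  # baseline subtraction shifts the threshold, not the slope
  resb <- cpp_slope(flat, baseline = 1.2)
  expect_equal(resb$threshold, 2.0, tolerance = 1e-6)
  expect_error(cpp_slope(ep, slope_window = c(-5, -4)), "window")
})

test_that("contralateral mu-beta shows planted lateralization", {
  set.seed(21)
  srate <- 250
  tt <- seq(-0.8, 0.2, by = 1 / srate)
  n_tr <- 20
  side <- rep(c("left", "right"), each = n_tr / 2)
  dat <- array(rnorm(4 * length(tt) * n_tr, 0, 0.1),
               dim = c(4, length(tt), n_tr))
  for (i in seq_len(n_tr)) {
    contra_ch <- if (side[i] == "left") 4 else 3 # C4 contra to left hand
    ipsi_ch <- if (side[i] == "left") 3 else 4
    dat[ipsi_ch, , i] <- dat[ipsi_ch, , i] +
      2 * sin(2 * pi * 20 * tt)
    dat[contra_ch, , i] <- dat[contra_ch, , i] +
      0.5 * sin(2 * pi * 20 * tt)
  }
  ep <- maat_epochs(dat, srate, tt, "response", c("Cz", "Pz", "C3", "C4"))
  res <- mubeta_slope(ep, side)
  pre <- res$time >= -0.4 & res$time <= -0.1
  expect_lt(mean(res$contra[pre]), mean(res$ipsi[pre]))
  # no lateralized plant -> contra ~ ipsi
  dat0 <- array(rnorm(4 * length(tt) * n_tr, 0, 0.1),
                dim = c(4, length(tt), n_tr))
  for (i in seq_len(n_tr)) for (ch in 3:4) {
    dat0[ch, , i] <- dat0[ch, , i] + sin(2 * pi * 20 * tt)
  }
  ep0 <- maat_epochs(dat0, srate, tt, "response",
                     c("Cz", "Pz", "C3", "C4"))
  res0 <- mubeta_slope(ep0, side)
  expect_lt(abs(mean(res0$contra[pre] - res0$ipsi[pre])),
            0.1 * mean(res0$ipsi[pre]))
  # missing response side drops the trial with a message
  expect_message(mubeta_slope(ep, replace(side, 1, NA)), "dropped")
})

test_that("ssvep normalization isolates the entrained component", {
  mk <- function(fun) make_epochs(fun, n_ch = 3, srate = 250,
                                  t_lim = c(-1.5, 3), n_trials = 4,
                                  channels = c("Pz", "POz", "Oz"))
  # pure 30 Hz during the whole epoch: positive normalized estimate
  ep <- mk(function(tt, c, tr) 0.8 * sin(2 * pi * 30 * tt))
  r <- ssvep_amplitude(ep)
  expect_gt(mean(r$raw), 0)
  # equal amplitude at 28/30/32 -> sideband subtraction cancels
  epf <- mk(function(tt, c, tr) {
    sin(2 * pi * 28 * tt) + sin(2 * pi * 30 * tt) + sin(2 * pi * 32 * tt)
  })
  rf <- ssvep_amplitude(epf)
  expect_lt(abs(mean(rf$raw)), 0.05 * mean(r$raw))
  # aperiodic background only: cancels within linear-sideband error
  set.seed(3)
  epn <- mk(function(tt, c, tr)
    maatkit:::colored_noise(length(tt), 250, 1.5))
  rn <- ssvep_amplitude(epn)
  expect_lt(abs(mean(rn$raw)), 0.1 * mean(r$raw))
  expect_error(ssvep_amplitude(ep, f0 = 124), "outside")
})

test_that("optimized entropy counts equal the brute-force oracle exactly", {
  set.seed(31)
  for (rep in 1:20) {
    n_seg <- sample(2:5, 1)
    lens <- sample(20:60, n_seg, replace = TRUE)
    segs <- lapply(lens, function(l) rnorm(l))
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.8) * sd(unlist(segs))
    bf <- sampen_bruteforce(segs, m, r)
    cc <- maatkit:::.sampen_counts_cpp(unlist(segs),
                                       rep(seq_len(n_seg), lens),
                                       as.integer(m), r)
    expect_identical(unname(bf["A"]), unname(cc[["A"]]))
    expect_identical(unname(bf["B"]), unname(cc[["B"]]))
  }
})

test_that("entropy behaves like an irregularity measure", {
  # strictly alternating (period-2) sequence, small r: A/B = 1, H = 0
  x <- rep(c(1, -1), 60)
  cc <- maatkit:::.sampen_counts_cpp(x, rep(1L, length(x)), 2L, 0.05)
  expect_gt(cc[["B"]], 0)
  expect_equal(cc[["A"]] / cc[["B"]], 1)
  # white noise more entropic than a sinusoid at matched variance
  set.seed(5)
  tt <- seq(0, 4, by = 1 / 250)
  noise <- rnorm(length(tt))
  sine <- sqrt(2) * sin(2 * pi * 5 * tt)
  ent <- function(x) {
    cc <- maatkit:::.sampen_counts_cpp(x, rep(1L, length(x)), 2L,
                                       0.5 * sd(x))
    -log(cc[["A"]] / cc[["B"]])
  }
  expect_gt(ent(noise), ent(sine))
})

test_that("time-resolved entropy flags undefined windows and drops alpha", {
  # constant signal -> undefined, never zero
  ep <- make_epochs(function(tt, c, tr) 0 * tt + 1, n_ch = 1,
                    n_trials = 3, t_lim = c(0, 2))
  e <- sample_entropy_timeresolved(ep, notch = NULL)
  expect_true(all(e$undefined))
  expect_true(all(is.na(e$entropy)))
  # notch removes an 8-15 Hz rhythm: notched entropy of a 10 Hz + noise
  # mix approaches that of the noise alone
  set.seed(6)
  epn <- make_epochs(function(tt, c, tr)
    rnorm(length(tt), 0, 0.5), n_ch = 1, n_trials = 4, t_lim = c(0, 2))
  epm <- make_epochs(function(tt, c, tr)
    3 * sin(2 * pi * 10 * tt) + rnorm(length(tt), 0, 0.5),
    n_ch = 1, n_trials = 4, t_lim = c(0, 2))
  en <- mean(sample_entropy_timeresolved(epn)$entropy, na.rm = TRUE)
  em_raw <- mean(sample_entropy_timeresolved(epm, notch = NULL)$entropy,
                 na.rm = TRUE)
  em_notch <- mean(sample_entropy_timeresolved(epm)$entropy, na.rm = TRUE)
  expect_lt(abs(em_notch - en), abs(em_raw - en))
})

test_that("aperiodic fits recover exponents with and without peaks", {
  f <- seq(2, 80, by = 0.5)
  fit <- aperiodic_fit(f, 10 * f^(-2))
  expect_equal(fit$exponent, 2, tolerance = 0.01)
  expect_equal(nrow(fit$peaks), 0)
  # power law + one Gaussian peak at 10 Hz
  psd <- 10 * f^(-1.5) + 5 * exp(-(f - 10)^2 / (2 * 1.5^2))
  fit2 <- aperiodic_fit(f, psd)
  expect_equal(fit2$exponent, 1.5, tolerance = 0.05)
  expect_gte(nrow(fit2$peaks), 1)
  expect_lt(abs(fit2$peaks$center[1] - 10), 2)
  # white-noise spectrum: exponent ~ 0
  fitw <- aperiodic_fit(f, rep(3, length(f)))
  expect_lt(abs(fitw$exponent), 0.01)
  expect_error(aperiodic_fit(f, -psd), "positive")
  expect_error(aperiodic_fit(f[1:5], psd[1:5]), "10")
})

test_that("exponent recovery is unbiased across a grid with planted peaks", {
  f <- seq(2, 80, by = 0.5)
  for (chi in c(0.5, 1, 1.5, 2, 2.5)) {
    psd <- 8 * f^(-chi) +
      4 * 8 * 10^(-chi) * exp(-(f - 10)^2 / (2 * 2^2)) +
      2 * 8 * 20^(-chi) * exp(-(f - 20)^2 / (2 * 2^2))
    fit <- aperiodic_fit(f, psd)
    expect_lt(abs(fit$exponent - chi), 0.05)
  }
})

test_that("frequency-domain filters are zero-phase", {
  # a symmetric input yields a symmetric output
  n <- 501
  x <- dnorm(seq(-3, 3, length.out = n)) + 0.2 * cos(
    2 * pi * 30 * seq(-1, 1, length.out = n))
  y <- fft_filter(x, srate = 250, high = 8)
  expect_equal(y, rev(y), tolerance = 1e-6)
  # band-stop removes the band, keeps the rest
  tt <- seq(0, 4, by = 1 / 250)
  sig <- sin(2 * pi * 10 * tt) + sin(2 * pi * 30 * tt)
  z <- fft_filter(sig, 250, low = 8, high = 15, stop = TRUE)
  pw <- function(x, f) {
    s <- fft(x); k <- round(f * 4) + 1; Mod(s[k])^2
  }
  expect_lt(pw(z, 10) / pw(sig, 10), 0.01)
  expect_gt(pw(z, 30) / pw(sig, 30), 0.9)
})
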