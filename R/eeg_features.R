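## Time-frequency, evidence-accumulation and excitability signatures.

#' Morlet wavelet time-frequency power
#'
#' Convolves each channel/trial with complex Morlet wavelets (default 7
#' cycles) and returns power on a decimated time grid. Power can be
#' log10-transformed at the single-trial level before any averaging, as
#' is standard for skewed spectral power.
#'
#' @param epochs a [maat_epochs].
#' @param freqs center frequencies (Hz), all below Nyquist.
#' @param n_cycles wavelet width in cycles.
#' @param step output step (s), default 50 ms.
#' @param log10_transform apply `log10` per trial (flag recorded).
#' @param average average across trials after the (optional) log.
#' @return a `maat_spectral` list: `power` (channel x freq x time
#'   [x trial if `average = FALSE`]), `freqs`, `time`, `log10`,
#'   `edge_valid` (logical per freq x time: outside the wavelet
#'   half-width of the epoch edges).
#' @export
morlet_power <- function(epochs, freqs, n_cycles = 7, step = 0.05,
                         log10_transform = TRUE, average = TRUE) {
  stopifnot(inherits(epochs, "maat_epochs"),
            max(freqs) < epochs$srate / 2)
  srate <- epochs$srate
  nt <- length(epochs$time)
  keep <- seq(1, nt, by = max(1L, round(step * srate)))
  out_t <- epochs$time[keep]
  nc <- dim(epochs$data)[1]; n_tr <- dim(epochs$data)[3]
  nf <- length(freqs)
  half_width <- (n_cycles / (2 * pi * freqs)) * 3.5 # 3.5 gaussian SDs
  edge_valid <- outer(half_width, out_t, function(hw, t) {
    t - min(epochs$time) >= hw & max(epochs$time) - t >= hw
  })
  nfft <- nextn(2L * nt)
  pow <- array(NA_real_, dim = c(nc, nf, length(keep), n_tr))
  for (fi in seq_len(nf)) {
    f0 <- freqs[fi]
    sd_t <- n_cycles / (2 * pi * f0)
    tk <- seq(-3.5 * sd_t, 3.5 * sd_t, by = 1 / srate)
    kern <- exp(-tk^2 / (2 * sd_t^2)) * exp(2i * pi * f0 * tk)
    kern <- kern / sum(abs(kern)) * 2 # amplitude-preserving norm
    kf <- fft(c(kern, rep(0, nfft - length(kern))))
    lag <- (length(tk) - 1) / 2
    for (ci in seq_len(nc)) {
      for (tr in seq_len(n_tr)) {
        x <- epochs$data[ci, , tr]
        cv <- fft(fft(c(x, rep(0, nfft - nt))) * kf, inverse = TRUE) / nfft
        amp2 <- Mod(cv[(lag + 1):(lag + nt)])^2
        pow[ci, fi, , tr] <- amp2[keep]
      }
    }
  }
  if (log10_transform) pow <- log10(pmax(pow, 1e-300))
  if (average) pow <- apply(pow, c(1, 2, 3), mean)
  structure(list(power = pow, freqs = freqs, time = out_t,
                 channels = epochs$channels, log10 = log10_transform,
                 step = step, n_cycles = n_cycles,
                 edge_valid = edge_valid),
            class = "maat_spectral")
}

slope_and_threshold <- function(trace, time, slope_window, thresh_window) {
  iw <- time >= slope_window[1] & time <= slope_window[2]
  it <- time >= thresh_window[1] & time <= thresh_window[2]
  if (!any(iw) || !any(it)) stop("analysis window outside epoch bounds")
  b <- ols_fit(time[iw], trace[iw])
  list(slope = unname(b["slope"]), threshold = mean(trace[it]))
}

#' Centro-parietal ramp slope and threshold amplitude
#'
#' Pre-response evidence-accumulation proxy: epochs (response-locked) are
#' low-pass filtered at 8 Hz (zero-phase, 6th-order Butterworth
#' magnitude), averaged across trials per condition over the given
#' channel set, optionally baseline-subtracted, and summarized by the
#' OLS slope over -250..-100 ms before the response plus the mean
#' amplitude within +/-50 ms of it (decision threshold proxy).
#'
#' @param epochs response-locked [maat_epochs].
#' @param channels channel labels to average (default: centro-parietal
#'   montage subset present in the data).
#' @param slope_window,thresh_window windows (s) relative to response.
#' @param baseline scalar (or per-trial vector) baseline to subtract,
#'   e.g. the condition mean over the final 250 ms before probe onset
#'   computed from probe-locked data; `NULL` for none.
#' @param trials optional trial subset (indices) defining the condition.
#' @param lowpass low-pass edge (Hz).
#' @return list with `slope` (units/s), `threshold`, `trace`, `time`,
#'   `window`, `channels`.
#' @export
cpp_slope <- function(epochs, channels = NULL,
                      slope_window = c(-0.25, -0.10),
                      thresh_window = c(-0.05, 0.05),
                      baseline = NULL, trials = NULL, lowpass = 8) {
  stopifnot(inherits(epochs, "maat_epochs"))
  if (is.null(channels)) {
    channels <- intersect(c("CPz", "Pz", "POz"), epochs$channels)
  }
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("unknown channels: ",
                      paste(channels[is.na(ci)], collapse = ", "))
  dat <- epochs$data[ci, , , drop = FALSE]
  if (!is.null(trials)) dat <- dat[, , trials, drop = FALSE]
  avg <- apply(dat, 2, mean) # channel- and trial-average
  avg <- fft_filter(avg, epochs$srate, high = lowpass, order = 6)
  if (!is.null(baseline)) avg <- avg - mean(baseline)
  st <- slope_and_threshold(avg, epochs$time, slope_window, thresh_window)
  c(st, list(trace = avg, time = epochs$time,
             window = slope_window, channels = channels))
}

#' Contralateral mu-beta power slope and threshold
#'
#' Band power (8-25 Hz, 7-cycle wavelets, 50 ms steps) is computed per
#' trial, channels are re-mapped to contra- and ipsilateral given each
#' trial's response side, trial-averaged, baseline-corrected per
#' condition, and the contralateral time course is summarized by the OLS
#' slope over -250..-50 ms pre-response and the mean within +/-50 ms.
#' Trials with missing response side are dropped (with a message).
#'
#' @param epochs response-locked [maat_epochs].
#' @param response_side per-trial `"left"`/`"right"` (NA dropped).
#' @param left_channels,right_channels motor channel labels.
#' @param baseline_window window (s) for baseline subtraction on the
#'   epoch's own axis, or `NULL`; classic pipelines use -400..-200 ms
#'   before probe onset from probe-locked data, passed via `baseline`.
#' @param baseline optional precomputed scalar baseline (overrides
#'   `baseline_window`).
#' @param slope_window,thresh_window summary windows (s).
#' @return list with `slope`, `threshold`, `contra`, `ipsi` (power time
#'   courses), `time`.
#' @export
mubeta_slope <- function(epochs, response_side,
                         left_channels = "C3", right_channels = "C4",
                         baseline_window = NULL, baseline = NULL,
                         slope_window = c(-0.25, -0.05),
                         thresh_window = c(-0.05, 0.05)) {
  stopifnot(inherits(epochs, "maat_epochs"),
            length(response_side) == dim(epochs$data)[3])
  keep <- !is.na(response_side)
  if (!all(keep)) {
    message(sum(!keep), " trial(s) dropped: missing response side")
  }
  sp <- morlet_power(epochs, freqs = seq(8, 25, by = 1), step = 0.05,
                     log10_transform = FALSE, average = FALSE)
  li <- match(left_channels, epochs$channels)
  ri <- match(right_channels, epochs$channels)
  if (anyNA(c(li, ri))) stop("motor channels not found in montage")
  side <- response_side[keep]
  trs <- which(keep)
  contra <- rep(0, length(sp$time)); ipsi <- rep(0, length(sp$time))
  for (i in seq_along(trs)) {
    if (side[i] == "left") { cc <- ri; ic <- li } else { cc <- li; ic <- ri }
    contra <- contra + apply(sp$power[cc, , , trs[i], drop = FALSE], 3, mean)
    ipsi <- ipsi + apply(sp$power[ic, , , trs[i], drop = FALSE], 3, mean)
  }
  contra <- contra / length(trs); ipsi <- ipsi / length(trs)
  if (is.null(baseline) && !is.null(baseline_window)) {
    bl <- sp$time >= baseline_window[1] & sp$time <= baseline_window[2]
    baseline <- mean(contra[bl])
  }
  if (!is.null(baseline)) {
    contra <- contra - baseline; ipsi <- ipsi - baseline
  }
  st <- slope_and_threshold(contra, sp$time, slope_window, thresh_window)
  c(st, list(contra = contra, ipsi = ipsi, time = sp$time))
}

#' Spectrally and temporally normalized steady-state response
#'
#' Estimates the 30 Hz entrained response via sliding 1 s Hann-tapered
#' FFTs (100 ms steps), removes broadband (aperiodic) contributions by
#' subtracting the mean of the 28 and 32 Hz sideband estimates, and
#' subtracts a pre-stimulus temporal baseline (-700..-100 ms window
#' centers by default).
#'
#' @param epochs stimulus-locked [maat_epochs].
#' @param f0 target frequency (Hz).
#' @param sidebands frequencies (Hz) averaged and subtracted.
#' @param window,step sliding FFT window and step (s).
#' @param baseline_window window-center range (s) for the temporal
#'   baseline.
#' @param channels channel subset (default posterior set if present).
#' @return list: `ssvep` (normalized time course), `time` (window
#'   centers), `raw` (before temporal baseline).
#' @export
ssvep_amplitude <- function(epochs, f0 = 30, sidebands = f0 + c(-2, 2),
                            window = 1, step = 0.1,
                            baseline_window = c(-0.7, -0.1),
                            channels = NULL) {
  stopifnot(inherits(epochs, "maat_epochs"))
  srate <- epochs$srate
  if (max(c(f0, sidebands)) >= srate / 2) {
    stop("target/sideband frequencies outside the spectrum")
  }
  if (is.null(channels)) {
    channels <- intersect(c("Pz", "POz", "Oz"), epochs$channels)
    if (!length(channels)) channels <- epochs$channels
  }
  ci <- match(channels, epochs$channels)
  nwin <- round(window * srate)
  starts <- seq(1, length(epochs$time) - nwin + 1,
                by = max(1L, round(step * srate)))
  centers <- epochs$time[starts] + window / 2
  hw <- hann_window(nwin)
  fbin <- function(f) round(f * window) + 1L # 1/window Hz resolution
  pw <- function(spec, f) Mod(spec[fbin(f)])^2
  n_tr <- dim(epochs$data)[3]
  est <- matrix(0, length(starts), n_tr)
  for (tr in seq_len(n_tr)) {
    x <- apply(epochs$data[ci, , tr, drop = FALSE], 2, mean)
    for (s in seq_along(starts)) {
      seg <- x[starts[s]:(starts[s] + nwin - 1)] * hw
      spec <- fft(seg) / nwin
      est[s, tr] <- pw(spec, f0) - mean(vapply(sidebands, pw,
                                               numeric(1), spec = spec))
    }
  }
  raw <- rowMeans(est)
  bl <- centers >= baseline_window[1] & centers <= baseline_window[2]
  if (!any(bl)) stop("temporal baseline window outside epoch")
  list(ssvep = raw - mean(raw[bl]), time = centers, raw = raw,
       channels = channels)
}

#' Time-resolved sample entropy across discontinuous segments
#'
#' Sample entropy (`-ln(A/B)`, `A` = length-`m+1` matches, `B` =
#' length-`m` matches, Chebyshev tolerance `r`) computed per sliding
#' window by pooling the window's samples across trials as discontinuous
#' segments: templates never span a trial boundary, but template pairs
#' may come from different trials. The tolerance is `r` times the pooled
#' standard deviation of all samples entering the window estimate
#' (recomputed per window, which implicitly normalizes by variance, so
#' no temporal baseline is applied). An 8-15 Hz band-stop (zero-phase,
#' 6th-order Butterworth magnitude) removes the alpha rhythm first.
#' Windows where `B = 0` or with zero variance are flagged undefined
#' (NA), never silently zeroed.
#'
#' @param epochs a [maat_epochs].
#' @param m template length (samples).
#' @param r tolerance as a fraction of the pooled within-window SD.
#' @param window,step window length and step (s).
#' @param notch two-sided band (Hz) to remove, or `NULL`.
#' @param channels channel subset (default all).
#' @return a `maat_entropy` list: `entropy` (channel x window matrix,
#'   nats), `time` (window centers), `undefined` (logical matrix), `m`,
#'   `r`, parameters.
#' @export
sample_entropy_timeresolved <- function(epochs, m = 2, r = 0.5,
                                        window = 0.5, step = 0.15,
                                        notch = c(8, 15),
                                        channels = NULL) {
  stopifnot(inherits(epochs, "maat_epochs"))
  srate <- epochs$srate
  if (is.null(channels)) channels <- epochs$channels
  ci <- match(channels, epochs$channels)
  nwin <- round(window * srate)
  starts <- seq(1, length(epochs$time) - nwin + 1,
                by = max(1L, round(step * srate)))
  centers <- epochs$time[starts] + window / 2
  n_tr <- dim(epochs$data)[3]
  ent <- matrix(NA_real_, length(ci), length(starts))
  undef <- matrix(FALSE, length(ci), length(starts))
  for (k in seq_along(ci)) {
    x <- epochs$data[ci[k], , , drop = FALSE][1, , ]
    x <- matrix(x, ncol = n_tr)
    if (!is.null(notch)) {
      x <- fft_filter(x, srate, low = notch[1], high = notch[2],
                      stop = TRUE, order = 6)
    }
    for (s in seq_along(starts)) {
      seg <- x[starts[s]:(starts[s] + nwin - 1), , drop = FALSE]
      pooled_sd <- sd(as.vector(seg))
      if (!is.finite(pooled_sd) || pooled_sd == 0) {
        undef[k, s] <- TRUE
        next
      }
      cnt <- .sampen_counts_cpp(as.vector(seg),
                                rep(seq_len(n_tr), each = nwin),
                                as.integer(m), r * pooled_sd)
      if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
        undef[k, s] <- TRUE
      } else {
        ent[k, s] <- -log(cnt[["A"]] / cnt[["B"]])
      }
    }
  }
  structure(list(entropy = ent, time = centers, undefined = undef,
                 m = m, r = r, window = window, step = step,
                 channels = channels),
            class = "maat_entropy")
}

#' Brute-force sample entropy match counts (oracle)
#'
#' Direct O(N^2) pairwise counting over the same discontinuous-segment
#' scheme as the optimized counter, written independently in R; used to
#' certify the compiled implementation by exact integer agreement.
#'
#' @param segments list of numeric vectors (one per trial segment).
#' @param m template length; @param r absolute tolerance.
#' @return named vector `A`, `B`.
#' @export
sampen_bruteforce <- function(segments, m, r) {
  tmpl <- list()
  for (s in seq_along(segments)) {
    x <- segments[[s]]
    n <- length(x)
    if (n < m + 1) next
    for (i in seq_len(n - m)) {
      tmpl[[length(tmpl) + 1L]] <- x[i:(i + m)] # m+1 samples
    }
  }
  A <- 0; B <- 0
  nt <- length(tmpl)
  if (nt >= 2) {
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        u <- tmpl[[i]]; v <- tmpl[[j]]
        if (max(abs(u[1:m] - v[1:m])) <= r) {
          B <- B + 1
          if (abs(u[m + 1] - v[m + 1]) <= r) A <- A + 1
        }
      }
    }
  }
  c(A = A, B = B)
}

#' Aperiodic (1/f) spectral fit with iterative peak exclusion
#'
#' Fits `log10(power) = offset - exponent * log10(f)` robustly: an OLS
#' line is fit, frequencies with strongly positive residuals (putative
#' oscillatory peaks) are flagged, the line is refit on non-peak points,
#' and the flag/refit cycle repeats until stable. Contiguous flagged
#' runs are reported as peaks (center, height above the aperiodic line,
#' width).
#'
#' @param freqs frequencies (Hz), positive.
#' @param psd power spectral density values (> 0) at `freqs`.
#' @param freq_range fitted range (Hz), default 2-80.
#' @param peak_threshold flag threshold in residual SDs.
#' @param min_peak_height minimum residual height (log10 power units)
#'   for a point to count as part of a peak; keeps numerically exact
#'   power laws from flagging rounding-level wiggles.
#' @param max_iter maximum refit cycles.
#' @return a `maat_aperiodic` list: `offset`, `exponent` (slope =
#'   -exponent in log-log), `peaks` (data.frame center/height/width),
#'   `resid_sd`, `freq_range`, `n_points`.
#' @export
aperiodic_fit <- function(freqs, psd, freq_range = c(2, 80),
                          peak_threshold = 2.0, min_peak_height = 0.05,
                          max_iter = 10) {
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2]
  f <- freqs[sel]; p <- psd[sel]
  if (any(p <= 0)) stop("PSD must be positive on the fitted range")
  lf <- log10(f); lp <- log10(p)
  mask <- rep(TRUE, length(f)) # TRUE = used in fit (non-peak)
  for (it in seq_len(max_iter)) {
    if (sum(mask) < 10) stop("fewer than 10 non-peak points in fit range")
    b <- ols_fit(lf[mask], lp[mask])
    resid <- lp - (b["intercept"] + b["slope"] * lf)
    new_mask <- resid <= pmax(peak_threshold * sd(resid[mask]),
                              min_peak_height)
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  resid <- lp - (b["intercept"] + b["slope"] * lf)
  peaks <- data.frame(center = numeric(), height = numeric(),
                      width = numeric())
  flagged <- !mask
  if (any(flagged)) {
    runs <- rle(flagged)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (ri in which(runs$values)) {
      idx <- starts[ri]:ends[ri]
      top <- idx[which.max(resid[idx])]
      peaks <- rbind(peaks, data.frame(center = f[top],
                                       height = resid[top],
                                       width = diff(range(f[idx])) +
                                         mean(diff(f))))
    }
  }
  structure(list(offset = unname(b["intercept"]),
                 exponent = unname(-b["slope"]),
                 peaks = peaks, resid_sd = sd(resid[mask]),
                 freq_range = freq_range, n_points = sum(mask)),
            class = "maat_aperiodic")
}

#' Hann-tapered zero-padded power spectral density
#'
#' PSD of epoched data over a time window: Hann-tapered segments,
#' zero-padded to a long window for fine frequency spacing, averaged
#' over trials and channels.
#'
#' @param epochs a [maat_epochs].
#' @param time_window window (s) on the epoch axis.
#' @param channels channel subset.
#' @param pad_to zero-padded length (s), giving `1/pad_to` Hz spacing.
#' @return list `freqs`, `psd`.
#' @export
psd_hann <- function(epochs, time_window = NULL, channels = NULL,
                     pad_to = 20) {
  stopifnot(inherits(epochs, "maat_epochs"))
  if (is.null(channels)) channels <- epochs$channels
  ci <- match(channels, epochs$channels)
  sel <- if (is.null(time_window)) rep(TRUE, length(epochs$time)) else
    epochs$time >= time_window[1] & epochs$time <= time_window[2]
  n <- sum(sel)
  nfft <- round(pad_to * epochs$srate)
  hw <- hann_window(n)
  freqs <- seq(0, epochs$srate / 2, by = 1 / pad_to)
  acc <- numeric(length(freqs))
  n_tr <- dim(epochs$data)[3]
  cnt <- 0
  for (tr in seq_len(n_tr)) {
    for (c in ci) {
      x <- epochs$data[c, sel, tr]
      x <- (x - mean(x)) * hw
      spec <- fft(c(x, rep(0, nfft - n)))
      px <- Mod(spec[seq_along(freqs)])^2 / (sum(hw^2) * epochs$srate)
      acc <- acc + px
      cnt <- cnt + 1
    }
  }
  list(freqs = freqs, psd = acc / cnt)
}
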