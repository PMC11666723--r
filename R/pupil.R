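## Pupillometry cleaning and the first-derivative arousal signature.

mask_to_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Clean a pupil trace set
#'
#' Flags samples inside blink annotations and samples where the
#' z-scored first derivative of the vertical gaze channel (by default;
#' optionally the pupil channel itself) exceeds `z_thresh` SDs, extends
#' every flagged stretch by `pad` seconds on both sides, and linearly
#' interpolates across the flagged gaps. Edge gaps cannot be
#' interpolated without extrapolating and stay missing (NA). Trials with
#' more than half their samples flagged are rejected (diameter set to
#' all-NA, reason recorded).
#'
#' @param pupil a `maat_pupil` from [simulate_pupil()] (or a compatible
#'   list: `diameter` trial x time, `time`, `srate`, `blinks`,
#'   optionally `gaze_y`).
#' @param z_thresh derivative outlier threshold (SDs).
#' @param pad padding around flagged samples (s).
#' @param screen_channel `"gaze"` (default, derivative of vertical eye
#'   position) or `"pupil"`.
#' @return the input with `diameter` cleaned, plus `flagged` (logical
#'   trial x time), `rejected` (per-trial logical) and
#'   `rejection_reason`.
#' @export
preprocess_pupil <- function(pupil, z_thresh = 3, pad = 0.15,
                             screen_channel = c("gaze", "pupil")) {
  screen_channel <- match.arg(screen_channel)
  d <- pupil$diameter
  n_tr <- nrow(d); n <- ncol(d)
  srate <- pupil$srate
  pad_n <- round(pad * srate)
  flagged <- matrix(FALSE, n_tr, n)
  src <- if (screen_channel == "gaze" && !is.null(pupil$gaze_y))
    pupil$gaze_y else d
  for (i in seq_len(n_tr)) {
    fl <- rep(FALSE, n)
    if (nrow(pupil$blinks)) {
      bl <- pupil$blinks[pupil$blinks$trial == i, , drop = FALSE]
      for (b in seq_len(nrow(bl))) {
        fl <- fl | (pupil$time >= bl$start[b] & pupil$time <= bl$end[b])
      }
    }
    dv <- c(0, diff(src[i, ]))
    z <- (dv - mean(dv)) / sd(dv)
    fl <- fl | abs(z) >= z_thresh
    if (any(fl)) { # dilate by pad on both sides
      runs <- mask_to_runs(fl)
      for (r in seq_len(nrow(runs))) {
        lo <- max(1, runs[r, "start"] - pad_n)
        hi <- min(n, runs[r, "end"] + pad_n)
        fl[lo:hi] <- TRUE
      }
    }
    flagged[i, ] <- fl
  }
  rejected <- rowMeans(flagged) > 0.5
  reason <- ifelse(rejected, ">50% samples flagged", "")
  out <- d
  for (i in seq_len(n_tr)) {
    if (rejected[i]) { out[i, ] <- NA_real_; next }
    fl <- flagged[i, ]
    if (!any(fl)) next
    good <- which(!fl)
    # interpolate interior gaps only; edge gaps stay missing
    interp <- approx(good, d[i, good], xout = seq_len(n),
                     method = "linear", rule = 1)$y
    out[i, ] <- ifelse(fl, interp, d[i, ])
  }
  pupil$diameter <- out
  pupil$flagged <- flagged
  pupil$rejected <- rejected
  pupil$rejection_reason <- reason
  pupil
}

decimate_mean <- function(x, factor) {
  # anti-aliased decimation: FFT low-pass at 0.8 * new Nyquist, then pick
  n <- length(x)
  keep <- seq(1, n, by = factor)
  if (factor == 1) return(x)
  miss <- is.na(x)
  if (all(miss)) return(x[keep])
  xi <- x
  if (any(miss)) { # temporary fill for filtering; missingness reimposed
    good <- which(!miss)
    xi <- approx(good, x[good], xout = seq_len(n), rule = 2)$y
  }
  xf <- fft_filter(xi, srate = 1, high = 0.8 * (1 / factor) / 2, order = 8)
  out <- xf[keep]
  out[miss[keep]] <- NA_real_
  out
}

#' Rate-of-change (first derivative) pupil signature
#'
#' First difference scaled by the sampling rate (units/s), computed at
#' the native rate, anti-alias decimated to `out_rate`, then smoothed
#' with a moving median. Any smoothing window containing a missing
#' sample is missing in the output (missingness propagates; silent
#' zero-filling would bias downstream load slopes).
#'
#' @param pupil a cleaned `maat_pupil` (see [preprocess_pupil()]).
#' @param out_rate output sampling rate (Hz).
#' @param median_window moving-median window (s).
#' @return a `maat_pupil_derivative` list: `rate` (trial x time,
#'   units/s), `time`, `srate = out_rate`, `median_window`, `load`.
#' @export
derivative_signature <- function(pupil, out_rate = 100,
                                 median_window = 0.3) {
  srate <- pupil$srate
  fac <- max(1L, round(srate / out_rate))
  n <- ncol(pupil$diameter)
  k <- round(median_window * out_rate)
  if (k %% 2 == 0) k <- k + 1
  n_out <- length(seq(1, n, by = fac))
  if (n_out < k) stop("trace shorter than the smoothing window")
  rate <- matrix(NA_real_, nrow(pupil$diameter), n_out)
  for (i in seq_len(nrow(pupil$diameter))) {
    x <- pupil$diameter[i, ]
    dv <- c(NA, diff(x)) * srate
    dd <- decimate_mean(dv, fac)
    miss <- is.na(dd)
    sm <- dd
    if (!all(miss)) {
      tmp <- dd; tmp[miss] <- median(dd, na.rm = TRUE)
      sm <- as.numeric(runmed(tmp, k, endrule = "median"))
      # propagate missingness through the median window
      miss_any <- as.logical(stats::filter(as.numeric(miss),
                                           rep(1, k), sides = 2) > 0)
      miss_any[is.na(miss_any)] <- miss[is.na(miss_any)]
      sm[miss_any] <- NA_real_
    }
    rate[i, ] <- sm
  }
  structure(list(rate = rate, time = pupil$time[seq(1, n, by = fac)],
                 srate = out_rate, median_window = median_window,
                 load = pupil$load, alignment = pupil$alignment),
            class = "maat_pupil_derivative")
}
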