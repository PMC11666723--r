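#' Derive a reproducible child seed from a session seed
#'
#' All randomness in the synthetic-data generators flows from a single
#' session seed; each modality draws from its own child stream obtained by
#' hashing the parent seed together with a stream label. The hash is a
#' plain multiplicative congruential mix, chosen so child seeds are stable
#' across platforms and stay below `2^31`.
#'
#' @param seed integer parent seed.
#' @param label character stream label (e.g. `"eeg"`, `"pupil"`).
#' @return integer child seed in `[0, 2^31 - 1]`.
#' @export
split_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 69069 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Zero-phase frequency-domain filter with Butterworth magnitude response
#'
#' Applies `|H(f)|^2 = prod 1/(1 + (f/fc)^(2*order))` style gains directly
#' in the frequency domain. This equals the magnitude response of
#' forward-backward (zero-phase) IIR Butterworth filtering and introduces
#' no phase distortion by construction; a symmetric input yields a
#' symmetric output. Used where classic pipelines call `filtfilt`.
#'
#' @param x numeric vector or matrix (filtering along columns).
#' @param srate sampling rate in Hz.
#' @param low high-pass edge in Hz (`NULL` for none).
#' @param high low-pass edge in Hz (`NULL` for none).
#' @param order Butterworth order of the equivalent one-pass filter.
#' @param stop if `TRUE`, `low`..`high` is a band-stop (notch) instead of a
#'   pass band.
#' @return filtered data, same shape as `x`.
#' @export
fft_filter <- function(x, srate, low = NULL, high = NULL, order = 6,
                       stop = FALSE) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  # mirror-pad to soften edge wrap-around
  pad <- min(n, max(16L, ceiling(srate)))
  xp <- rbind(xm[pad:1, , drop = FALSE], xm, xm[n:(n - pad + 1), , drop = FALSE])
  np <- nrow(xp)
  f <- (seq_len(np) - 1) / np * srate
  f <- pmin(f, srate - f) # two-sided frequency magnitude
  gain <- rep(1, np)
  if (!is.null(high)) gain <- gain / sqrt(1 + (f / high)^(2 * order))
  if (!is.null(low))  gain <- gain / sqrt(1 + ifelse(f > 0, (low / f)^(2 * order), Inf))
  if (stop) {
    stopifnot(!is.null(low), !is.null(high))
    bp <- 1 / sqrt(1 + (f / high)^(2 * order)) *
      1 / sqrt(1 + ifelse(f > 0, (low / f)^(2 * order), Inf))
    gain <- 1 - bp
  }
  out <- apply(xp, 2, function(col) {
    Re(fft(fft(col) * gain, inverse = TRUE)) / np
  })
  out <- out[(pad + 1):(pad + n), , drop = FALSE]
  if (vec) drop(out) else out
}

#' @keywords internal
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' @keywords internal
ols_fit <- function(x, y) {
  # closed-form simple OLS; returns c(intercept, slope)
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}

#' @keywords internal
stable_hash <- function(x) {
  # FNV-1a over the serialized JSON of x; provenance stamp, not crypto
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (ch in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
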