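## Simplified first-level GLM for BOLD-like time series.

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-convention double gamma: peak near 5-6 s, undershoot near 16 s
#' with 1/6 relative amplitude, unit peak height.
#'
#' @param t time (s).
#' @return HRF values.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

#' Build a first-level design matrix
#'
#' Boxcars per condition are convolved with the canonical double-gamma
#' HRF; each condition also contributes a temporal-derivative nuisance
#' column. Parametric modulators are mean-centered within condition
#' before convolution (a constant modulator therefore yields an all-zero
#' column). Arbitrary nuisance columns may be appended. Regressors are
#' causal: zero before the first onset.
#'
#' @param events data.frame: `onset` (s, non-decreasing), `duration`
#'   (s, > 0), `condition`, optionally `modulator` (named numeric
#'   columns prefixed `mod_`).
#' @param TR repetition time (s).
#' @param n_volumes scan length in volumes.
#' @param nuisance optional matrix of nuisance columns (time x k).
#' @param oversample HRF convolution grid (samples per TR).
#' @param check_rank error on rank deficiency, naming collinear columns.
#' @return a `maat_design_matrix`: `X` (volume x regressor), `names`,
#'   `TR`, `condition_columns` (the task regressors of interest).
#' @export
build_design <- function(events, TR, n_volumes, nuisance = NULL,
                         oversample = 16, check_rank = TRUE) {
  stopifnot(all(diff(events$onset) >= 0), all(events$duration > 0))
  if (max(events$onset + events$duration) > n_volumes * TR) {
    stop("events extend beyond scan duration")
  }
  dt <- TR / oversample
  n_hi <- n_volumes * oversample
  t_hi <- (seq_len(n_hi) - 1) * dt
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  conv_down <- function(stick) {
    cv <- convolve(stick, rev(hrf), type = "open")[seq_len(n_hi)]
    cv[seq(1, n_hi, by = oversample)]
  }
  conds <- unique(events$condition)
  mod_cols <- grep("^mod_", names(events), value = TRUE)
  cols <- list(); nm <- character(0); task <- character(0)
  for (cc in conds) {
    ev <- events[events$condition == cc, , drop = FALSE]
    stick <- numeric(n_hi)
    for (i in seq_len(nrow(ev))) {
      sel <- t_hi >= ev$onset[i] & t_hi < ev$onset[i] + ev$duration[i]
      stick[sel] <- 1
    }
    reg <- conv_down(stick)
    cols[[length(cols) + 1L]] <- reg
    nm <- c(nm, cc); task <- c(task, cc)
    # temporal derivative as nuisance
    cols[[length(cols) + 1L]] <- c(0, diff(reg))
    nm <- c(nm, paste0(cc, "_tderiv"))
    for (mc in mod_cols) {
      mv <- ev[[mc]]
      if (all(!is.finite(mv))) next
      mv <- mv - mean(mv) # mean-centered within condition
      stick_m <- numeric(n_hi)
      for (i in seq_len(nrow(ev))) {
        sel <- t_hi >= ev$onset[i] & t_hi < ev$onset[i] + ev$duration[i]
        stick_m[sel] <- mv[i]
      }
      cols[[length(cols) + 1L]] <- conv_down(stick_m)
      nm <- c(nm, paste0(cc, "_", sub("^mod_", "", mc)))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, intercept = 1)
  keep <- apply(X, 2, function(cl) any(cl != 0))
  X <- X[, keep, drop = FALSE]
  if (check_rank) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      stop("design matrix rank-deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(X = X, names = colnames(X), TR = TR,
                 condition_columns = task),
            class = "maat_design_matrix")
}

#' Fit a first-level GLM per voxel
#'
#' Ordinary least squares per voxel (white-noise assumption; see the
#' methods vignette for why autoregressive whitening is out of scope for
#' planted-effect recovery). With a `run` vector, each run is fit
#' separately and condition betas are averaged across runs.
#'
#' @param timeseries numeric matrix, voxel x time (all runs
#'   concatenated when `run` is given).
#' @param design a `maat_design_matrix`, or a list of them (one per
#'   run).
#' @param run optional run label per time point.
#' @return a `maat_betamap`: `betas` (voxel x regressor, run-averaged
#'   for condition columns), `resid_var` per voxel, `names`.
#' @export
fit_glm <- function(timeseries, design, run = NULL) {
  if (anyNA(timeseries) || any(!is.finite(timeseries))) {
    stop("non-finite values in time series")
  }
  fit_one <- function(Y, D) {
    stopifnot(ncol(Y) == nrow(D$X))
    f <- lm.fit(D$X, t(Y))
    bt <- t(f$coefficients)
    rv <- colSums(as.matrix(f$residuals)^2) /
      (nrow(D$X) - ncol(D$X))
    list(betas = bt, resid_var = rv)
  }
  if (is.null(run)) {
    r <- fit_one(timeseries, design)
    out <- list(betas = r$betas, resid_var = r$resid_var,
                names = colnames(r$betas),
                condition_columns = design$condition_columns)
  } else {
    runs <- unique(run)
    designs <- if (inherits(design, "maat_design_matrix"))
      rep(list(design), length(runs)) else design
    fits <- lapply(seq_along(runs), function(i) {
      fit_one(timeseries[, run == runs[i], drop = FALSE], designs[[i]])
    })
    cond <- designs[[1]]$condition_columns
    bmats <- lapply(fits, function(f) f$betas[, cond, drop = FALSE])
    betas <- Reduce(`+`, bmats) / length(bmats)
    out <- list(betas = betas,
                resid_var = rowMeans(vapply(fits, function(f)
                  f$resid_var, numeric(nrow(timeseries)))),
                names = cond, condition_columns = cond)
  }
  class(out) <- "maat_betamap"
  out
}
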