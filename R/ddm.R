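#' Drift-diffusion parameter set
#'
#' Accuracy-coded parameterization with unit diffusion: drift `v` points
#' toward the correct bound, `a` is the separation between correct and
#' incorrect bounds, `t0` the non-decision time, `w` the (fixed) relative
#' start point, `p_outlier` the mixture weight of uniform-RT outliers.
#'
#' @param v drift rate (evidence units / s, signed toward correct bound).
#' @param a boundary separation (> 0).
#' @param t0 non-decision time (s, >= 0).
#' @param w relative start point in (0, 1); fixed at 0.5 for
#'   accuracy-coded data.
#' @param p_outlier outlier mixture probability in `[0, 1)`.
#' @param load optional condition label (target load 1-4).
#' @return a `maat_ddm_params` list.
#' @export
ddm_params <- function(v, a, t0, w = 0.5, p_outlier = 0.05, load = NA) {
  stopifnot(is.finite(v), a > 0, t0 >= 0, w > 0, w < 1,
            p_outlier >= 0, p_outlier < 1)
  structure(list(v = v, a = a, t0 = t0, w = w, p_outlier = p_outlier,
                 load = load),
            class = c("maat_ddm_params", "list"))
}

#' Simulate trials from the diffusion first-passage process
#'
#' Euler-discretized diffusion with a Brownian-bridge correction for
#' within-step boundary crossings (so millisecond steps already match
#' the analytic first-passage density). When `p_outlier > 0`, that
#' fraction of trials (in expectation) is replaced by uniform-RT
#' outliers on `[0.25 s, max simulated RT]` with random accuracy.
#'
#' @param params a [ddm_params()].
#' @param n number of trials.
#' @param seed integer seed.
#' @param dt Euler step (s); must be <= 1 ms (a warning is raised beyond
#'   that, per the simulator's accuracy contract).
#' @param max_t censoring horizon (s) for the decision time.
#' @return data.frame with `rt` (s), `correct` (1 = correct bound),
#'   `outlier` flag.
#' @export
simulate_ddm_trials <- function(params, n, seed, dt = 1e-3, max_t = 10) {
  stopifnot(inherits(params, "maat_ddm_params"), n >= 1)
  if (missing(seed)) stop("seed must be given")
  if (dt > 1e-3 + 1e-12) {
    warning("dt > 1 ms violates the simulator accuracy contract")
  }
  sim <- .ddm_sim_cpp(as.integer(n), params$v, params$a, params$w,
                      params$t0, dt, max_t,
                      as.integer(split_seed(seed, "ddm")) %% 2^31)
  out <- data.frame(rt = sim$rt, correct = sim$upper,
                    outlier = FALSE)
  if (params$p_outlier > 0) {
    set.seed(split_seed(seed, "ddm_outlier"))
    is_out <- runif(n) < params$p_outlier
    if (any(is_out)) {
      hi <- max(out$rt)
      out$rt[is_out] <- runif(sum(is_out), 0.25, hi)
      out$correct[is_out] <- rbinom(sum(is_out), 1, 0.5)
      out$outlier[is_out] <- TRUE
    }
  }
  out
}

#' First-passage time density of the diffusion decision process
#'
#' Density of absorption at the correct or error bound at response time
#' `t` (including the non-decision shift). Evaluated through the
#' small-time / large-time series split with truncation chosen by the
#' standard error bound (series tolerance `1e-10` on the normalized
#' density).
#'
#' @param t response times (s).
#' @param params a [ddm_params()].
#' @param boundary `"correct"` or `"error"` (recycled over `t`).
#' @return density values (1/s); 0 for `t <= t0`.
#' @export
first_passage_density <- function(t, params,
                                  boundary = c("correct", "error")) {
  stopifnot(inherits(params, "maat_ddm_params"))
  if (!all(is.finite(unlist(params[c("v", "a", "t0", "w")]))))
    stop("non-finite parameters")
  boundary <- match.arg(boundary, several.ok = TRUE)
  boundary <- rep(boundary, length.out = length(t))
  up <- as.integer(boundary == "correct")
  td <- t - params$t0
  dens <- numeric(length(t))
  ok <- td > 0
  if (any(ok)) {
    dens[ok] <- .wfpt_density_cpp(td[ok], params$v, params$a, params$w,
                                  up[ok], 1e-10)
  }
  dens
}

## ---------------------------------------------------------------------
## Maximum-likelihood fitting

DDM_VARIANTS <- c("full", "drift", "drift_threshold", "drift_ndt", "null")

ez_start <- function(rt, correct) {
  # EZ-diffusion moment inversion as optimizer starting values
  n <- length(rt)
  pc <- (sum(correct) + 0.5) / (n + 1)          # edge-corrected accuracy
  pc <- min(max(pc, 0.52), 0.98)
  vrt <- var(rt[correct == 1])
  if (!is.finite(vrt) || vrt <= 0) vrt <- max(var(rt), 0.01)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^(1 / 4)
  v <- min(max(v, 0.2), 6)
  a <- min(max(L / v, 0.5), 4)
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- max(mean(rt) - mdt, 0.08)
  c(v = v, a = a, t0 = min(t0, min(rt) - 0.01))
}

mixture_negll <- function(rt, correct, v, a, t0, p_outlier, unif_span) {
  up <- as.integer(correct == 1)
  td <- rt - t0
  f <- numeric(length(rt))
  ok <- td > 1e-5
  if (any(ok)) {
    f[ok] <- .wfpt_density_cpp(td[ok], v, a, 0.5, up[ok], 1e-10)
  }
  dens <- (1 - p_outlier) * f + p_outlier / (2 * unif_span)
  dens[dens < 1e-300] <- 1e-300
  -sum(log(dens))
}

#' Fit the diffusion model to one subject's trials
#'
#' Maximum-likelihood fitting of the outlier-mixture likelihood
#' `(1 - p_outlier) * f_wiener + p_outlier * uniform`, with premature
#' responses (< 250 ms) excluded before fitting. The uniform outlier
#' component spans `[0.25 s, max observed RT]` over both response
#' categories. Five nested variants fix parameters across load
#' conditions: `"full"` lets drift, boundary separation and non-decision
#' time all vary by condition (and therefore factorizes into independent
#' per-condition fits); `"drift"`, `"drift_threshold"` and `"drift_ndt"`
#' free the named subsets; `"null"` shares all three. The start point is
#' fixed at 0.5 (accuracy coding).
#'
#' @param trials data.frame with columns `rt`, `correct`, `load` (one
#'   subject).
#' @param variant one of `"full"`, `"drift"`, `"drift_threshold"`,
#'   `"drift_ndt"`, `"null"`.
#' @param p_outlier fixed outlier mixture weight (default 0.05).
#' @param min_per_condition minimum non-excluded trials per condition.
#' @return a `maat_ddm_fit`: per-condition parameter table, `logLik`,
#'   `n_params`, `aic`, `bic`, `variant`, `converged`.
#' @export
fit_ddm <- function(trials, variant = "full", p_outlier = 0.05,
                    min_per_condition = 20) {
  variant <- match.arg(variant, DDM_VARIANTS)
  keep <- trials$rt >= 0.25
  tr <- trials[keep, , drop = FALSE]
  loads <- sort(unique(tr$load))
  cnt <- table(tr$load)
  if (any(cnt < min_per_condition)) {
    stop("fewer than ", min_per_condition,
         " non-excluded trials in some condition")
  }
  span <- max(tr$rt) - 0.25
  k <- length(loads)
  by_ld <- split(tr, tr$load)
  starts <- lapply(by_ld, function(d) ez_start(d$rt, d$correct))
  lower <- c(v = -8, a = 0.3, t0 = 0.05)
  # with an outlier mixture, RTs below t0 carry outlier density, so t0
  # need not be bounded by min(rt); the median is a safe ceiling
  t0_cap <- if (p_outlier > 0) unname(quantile(tr$rt, 0.5))
            else min(tr$rt) - 1e-3
  upper_b <- c(v = 8, a = 5, t0 = max(0.06, t0_cap))

  fit_cell <- function(d, st) {
    cap <- if (p_outlier > 0) unname(quantile(d$rt, 0.5))
           else min(d$rt) - 1e-3
    nll <- function(p) mixture_negll(d$rt, d$correct, p[1], p[2], p[3],
                                     p_outlier, span)
    optim(pmin(st, c(8, 5, cap)), nll, method = "L-BFGS-B",
          lower = lower, upper = pmin(upper_b, c(8, 5, max(0.06, cap))))
  }

  if (variant == "full") {
    fits <- Map(fit_cell, by_ld, starts)
    ll <- -sum(vapply(fits, function(f) f$value, numeric(1)))
    conv <- all(vapply(fits, function(f) f$convergence == 0, logical(1)))
    par_tab <- data.frame(
      load = loads,
      v = vapply(fits, function(f) f$par[1], numeric(1)),
      a = vapply(fits, function(f) f$par[2], numeric(1)),
      t0 = vapply(fits, function(f) f$par[3], numeric(1)))
    n_par <- 3 * k
  } else {
    free_v <- TRUE # drift varies in every non-null variant
    free_a <- variant == "drift_threshold"
    free_t <- variant == "drift_ndt"
    if (variant == "null") free_v <- FALSE
    st_mat <- do.call(rbind, starts)
    st <- c(if (free_v) st_mat[, "v"] else mean(st_mat[, "v"]),
            if (free_a) st_mat[, "a"] else mean(st_mat[, "a"]),
            if (free_t) st_mat[, "t0"] else min(st_mat[, "t0"]))
    nv <- if (free_v) k else 1
    na <- if (free_a) k else 1
    nt <- if (free_t) k else 1
    unpack <- function(p) {
      v <- p[seq_len(nv)]; a <- p[nv + seq_len(na)]
      t0 <- p[nv + na + seq_len(nt)]
      list(v = rep(v, length.out = k), a = rep(a, length.out = k),
           t0 = rep(t0, length.out = k))
    }
    nll <- function(p) {
      q <- unpack(p)
      s <- 0
      for (j in seq_len(k)) {
        d <- by_ld[[j]]
        s <- s + mixture_negll(d$rt, d$correct, q$v[j], q$a[j], q$t0[j],
                               p_outlier, span)
      }
      s
    }
    lo <- c(rep(lower["v"], nv), rep(lower["a"], na), rep(lower["t0"], nt))
    hi <- c(rep(upper_b["v"], nv), rep(upper_b["a"], na),
            rep(upper_b["t0"], nt))
    o <- optim(st, nll, method = "L-BFGS-B", lower = lo, upper = hi)
    q <- unpack(o$par)
    ll <- -o$value
    conv <- o$convergence == 0
    par_tab <- data.frame(load = loads, v = q$v, a = q$a, t0 = q$t0)
    n_par <- nv + na + nt
  }
  n_obs <- nrow(tr)
  res <- list(params = par_tab, logLik = ll, n_params = n_par,
              aic = -2 * ll + 2 * n_par,
              bic = -2 * ll + log(n_obs) * n_par,
              variant = variant, converged = conv,
              n_trials = n_obs, n_excluded = sum(!keep),
              p_outlier = p_outlier,
              trial_checksum = round(sum(tr$rt), 6))
  class(res) <- "maat_ddm_fit"
  res
}

#' @export
print.maat_ddm_fit <- function(x, ...) {
  cat(sprintf("<maat_ddm_fit> variant=%s logLik=%.2f AIC=%.1f (%d params, %d trials%s)\n",
              x$variant, x$logLik, x$aic, x$n_params, x$n_trials,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$params, digits = 3)
  invisible(x)
}

#' Rank fitted diffusion-model variants by information criterion
#'
#' All variants must have been fitted to the identical trial set; ranking
#' is by the complexity-penalized criterion (lower is better). AIC/BIC
#' replace the deviance information criterion used with hierarchical
#' sampling.
#'
#' @param fits list of `maat_ddm_fit` objects.
#' @param criterion `"aic"` or `"bic"`.
#' @return data.frame ranked best-first with variant, logLik, n_params,
#'   criterion value and delta to the best.
#' @export
compare_models <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "maat_ddm_fit")))
  ns <- vapply(fits, function(f) f$n_trials, numeric(1))
  cs <- vapply(fits, function(f) f$trial_checksum, numeric(1))
  if (length(unique(ns)) != 1 || length(unique(cs)) != 1) {
    stop("variants were not fitted on identical trial sets")
  }
  tab <- data.frame(
    variant = vapply(fits, function(f) f$variant, character(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    ic = vapply(fits, function(f) f[[criterion]], numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)))
  tab <- tab[order(tab$ic), ]
  tab$delta <- tab$ic - tab$ic[1]
  names(tab)[names(tab) == "ic"] <- criterion
  rownames(tab) <- NULL
  tab
}
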