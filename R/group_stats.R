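## Group-level statistical utilities: linear load slopes, MAD
## winsorization, within-subject centering, cluster-based permutation
## tests, random-intercept models.

#' Per-subject linear uncertainty (target load) slopes
#'
#' Fits `y = intercept + beta * load + e` by OLS for every subject and
#' returns the first-level betas, plus the standard group tests: a
#' two-sided one-sample t-test of the slopes against zero within each
#' group and a two-sided two-sample t-test between groups (when two
#' groups are present).
#'
#' @param table data.frame with columns `subject`, `load`, `value` and
#'   optionally `group`.
#' @return list: `slopes` (subject, group, intercept, beta),
#'   `within_group` (t-test per group), `between_group` (or `NULL`).
#' @export
linear_load_slope <- function(table) {
  stopifnot(all(c("subject", "load", "value") %in% names(table)))
  if (is.null(table$group)) table$group <- "all"
  sl <- do.call(rbind, lapply(split(table, table$subject), function(d) {
    if (length(unique(d$load)) < 2) {
      stop("subject ", d$subject[1], " has a single load level")
    }
    b <- ols_fit(d$load, d$value)
    data.frame(subject = d$subject[1], group = d$group[1],
               intercept = unname(b["intercept"]),
               beta = unname(b["slope"]), stringsAsFactors = FALSE)
  }))
  rownames(sl) <- NULL
  wt <- lapply(split(sl$beta, sl$group), function(b) {
    if (length(b) < 2 || sd(b) == 0) return(NULL)
    t.test(b, mu = 0)
  })
  bt <- NULL
  gl <- unique(sl$group)
  if (length(gl) == 2) {
    b1 <- sl$beta[sl$group == gl[1]]; b2 <- sl$beta[sl$group == gl[2]]
    if (min(length(b1), length(b2)) >= 2) {
      bt <- t.test(b1, b2, var.equal = FALSE)
    }
  }
  list(slopes = sl, within_group = wt, between_group = bt)
}

#' MAD winsorization within groups
#'
#' Values beyond `median +/- k` scaled median absolute deviations
#' (`1.4826 * median(|x - median|)`, the consistent-for-normal scaling)
#' are clipped to that bound, within each group. A zero MAD with spread
#' present is flagged degenerate.
#'
#' @param values numeric vector.
#' @param group optional grouping vector.
#' @param k bound in scaled MADs (default 3).
#' @return list: `values` (winsorized), `outlier` (logical flags),
#'   `degenerate` (per-group logical).
#' @export
mad_winsorize <- function(values, group = rep("all", length(values)),
                          k = 3) {
  out <- values
  flags <- rep(FALSE, length(values))
  degen <- c()
  for (g in unique(group)) {
    ix <- which(group == g)
    x <- values[ix]
    if (length(x) < 4) stop("need >= 4 values per group")
    med <- median(x)
    sm <- 1.4826 * median(abs(x - med))
    if (sm == 0) {
      degen[g] <- sd(x) > 0
      next
    }
    degen[g] <- FALSE
    lo <- med - k * sm; hi <- med + k * sm
    fl <- x < lo | x > hi
    out[ix] <- pmin(pmax(x, lo), hi)
    flags[ix] <- fl
  }
  list(values = out, outlier = flags, degenerate = degen)
}

#' Within-subject centering of repeated measures
#'
#' Subtracts each subject's cross-condition mean and adds back the
#' (group) grand mean, removing between-subject offset variance while
#' preserving condition means exactly — the standard construction for
#' within-subject error bars.
#'
#' @param table data.frame with `subject`, `condition`, `value`, and
#'   optionally `group` (centering is within group).
#' @return the table with `value` centered.
#' @export
within_subject_center <- function(table) {
  stopifnot(all(c("subject", "condition", "value") %in% names(table)))
  if (is.null(table$group)) table$group <- "all"
  tab <- table
  for (g in unique(tab$group)) {
    sel <- tab$group == g
    cells <- table(tab$subject[sel], tab$condition[sel])
    if (any(cells != 1)) stop("incomplete subject x condition cells")
    gm <- mean(tab$value[sel])
    sm <- tapply(tab$value[sel], tab$subject[sel], mean)
    tab$value[sel] <- tab$value[sel] -
      sm[as.character(tab$subject[sel])] + gm
  }
  tab
}

build_adjacency <- function(n_points, channel_of = NULL,
                            time_of = NULL, neighbors = NULL,
                            channels = NULL) {
  # adjacency list over points: temporal chain within channel plus
  # channel neighbors at the same time point
  adj <- vector("list", n_points)
  if (is.null(channel_of)) { # pure temporal chain
    for (i in seq_len(n_points)) {
      adj[[i]] <- c(if (i > 1) i - 1, if (i < n_points) i + 1)
    }
    return(adj)
  }
  for (i in seq_len(n_points)) {
    same_ch <- which(channel_of == channel_of[i] &
                       abs(time_of - time_of[i]) == 1)
    nb <- neighbors[[channels[channel_of[i]]]]
    same_t <- which(time_of == time_of[i] &
                      channels[channel_of] %in% nb)
    adj[[i]] <- c(same_ch, same_t)
  }
  adj
}

cluster_mass <- function(tvals, thresh, adj, channel_of = NULL,
                         min_channels = 3) {
  supra <- which(abs(tvals) > thresh)
  clusters <- list()
  seen <- logical(length(tvals))
  for (s in supra) {
    if (seen[s]) next
    # BFS over same-sign suprathreshold neighbors
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    sgn <- sign(tvals[s])
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      comp <- c(comp, p)
      for (q in adj[[p]]) {
        if (!seen[q] && abs(tvals[q]) > thresh && sign(tvals[q]) == sgn) {
          seen[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
    if (!is.null(channel_of) && min_channels > 1) {
      if (length(unique(channel_of[comp])) < min_channels) next
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(comp), mass = sum(tvals[comp]))
  }
  clusters
}

#' Cluster-based permutation test for dependent-sample designs
#'
#' One-sample (or paired-difference) t-tests at every point form
#' clusters of same-sign suprathreshold neighbors; with spatio-temporal
#' data a cluster must additionally span at least `min_channels`
#' neighboring channels. Cluster mass (summed t) is compared against a
#' sign-flip permutation null of maximal cluster masses.
#'
#' @param data numeric matrix, subject x point (within-subject
#'   differences for paired designs).
#' @param neighbors optional channel neighbor list; when given,
#'   `channel_of`/`time_of`/`channels` describe the point grid.
#' @param channel_of,time_of integer index per point into `channels`
#'   and the time grid (required with `neighbors`).
#' @param channels channel labels (required with `neighbors`).
#' @param entry_p two-sided per-point entry threshold.
#' @param n_perm Monte Carlo sign-flip iterations.
#' @param sig_p two-sided cluster significance threshold.
#' @param min_channels minimum neighboring channels per spatial cluster.
#' @param seed integer seed.
#' @return a `maat_cluster_test` list: `clusters` (members, mass, p,
#'   significant), `entry_threshold`, `n_perm`, `sig_p`, `max_null`.
#' @export
cluster_permutation_test <- function(data, neighbors = NULL,
                                     channel_of = NULL, time_of = NULL,
                                     channels = NULL,
                                     entry_p = 0.05, n_perm = 1000,
                                     sig_p = 0.025, min_channels = 3,
                                     seed = 1) {
  data <- as.matrix(data)
  n_sub <- nrow(data); n_pt <- ncol(data)
  stopifnot(n_sub >= 2)
  tcrit <- qt(1 - entry_p / 2, df = n_sub - 1)
  tstat <- function(d) {
    m <- colMeans(d)
    se <- apply(d, 2, sd) / sqrt(n_sub)
    ifelse(se > 0, m / se, 0)
  }
  adj <- build_adjacency(n_pt, channel_of, time_of, neighbors, channels)
  use_space <- !is.null(neighbors)
  obs <- cluster_mass(tstat(data), tcrit, adj,
                      if (use_space) channel_of else NULL, min_channels)
  set.seed(split_seed(seed, "cluster"))
  max_null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    cl <- cluster_mass(tstat(data * flips), tcrit, adj,
                       if (use_space) channel_of else NULL, min_channels)
    max_null[p] <- if (length(cl))
      max(vapply(cl, function(x) abs(x$mass), numeric(1))) else 0
  }
  clusters <- lapply(obs, function(cl) {
    cl$p <- (sum(max_null >= abs(cl$mass)) + 1) / (n_perm + 1)
    cl$significant <- cl$p < sig_p
    cl
  })
  structure(list(clusters = clusters, entry_threshold = tcrit,
                 entry_p = entry_p, n_perm = n_perm, sig_p = sig_p,
                 max_null = max_null),
            class = "maat_cluster_test")
}

#' Random-intercept model of load and age-group effects
#'
#' Fits `value ~ load + group (+ load:group) + (1 | subject)` with lme4;
#' per the stepwise convention, the interaction is dropped when not
#' significant and the main-effects model is refit. p-values use the
#' normal approximation to the Wald t (no Satterthwaite correction
#' available in the target environment). On non-convergence the
#' function falls back to the two-stage path (per-subject OLS slopes,
#' group t-tests) and flags it.
#'
#' @param table data.frame with `subject`, `group`, `load`, `value`.
#' @param drop_ns_interaction drop a non-significant (p >= 0.05)
#'   interaction and refit.
#' @return list: `fixed` (estimate, se, z, p per fixed effect),
#'   `interaction_kept`, `converged`, `fallback` (`NULL` or the
#'   two-stage [linear_load_slope()] result), `model`.
#' @export
random_intercept_model <- function(table, drop_ns_interaction = TRUE) {
  stopifnot(all(c("subject", "group", "load", "value") %in% names(table)))
  if (min(table(table$subject)) < 2) {
    stop("need >= 2 observations per subject")
  }
  two_group <- length(unique(table$group)) >= 2
  fe_tab <- function(fit) {
    cf <- summary(fit)$coefficients
    data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
               se = cf[, "Std. Error"], z = cf[, "t value"],
               p = 2 * pnorm(-abs(cf[, "t value"])),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- try({
    form <- if (two_group) value ~ load * group + (1 | subject)
            else value ~ load + (1 | subject)
    fit <- lme4::lmer(form, data = table, REML = TRUE)
    kept <- TRUE
    if (two_group && drop_ns_interaction) {
      tab <- fe_tab(fit)
      ip <- tab$p[grepl(":", tab$term)]
      if (length(ip) && all(ip >= 0.05)) {
        fit <- lme4::lmer(value ~ load + group + (1 | subject),
                          data = table, REML = TRUE)
        kept <- FALSE
      }
    }
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    list(fixed = fe_tab(fit), interaction_kept = kept,
         converged = conv, fallback = NULL, model = fit)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    message("mixed model failed; falling back to two-stage estimates")
    fb <- linear_load_slope(table)
    return(list(fixed = NULL, interaction_kept = NA, converged = FALSE,
                fallback = fb, model = NULL))
  }
  res
}
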