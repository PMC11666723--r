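## Pseudo-trial bootstrap linear decoding of binary feature options.

lda_ridge_classify <- function(train_x, train_y, test_x) {
  # Regularized linear discriminant in the high-regularization limit:
  # w = mu1 - mu0 (the ridge solution as lambda -> Inf, equivalently a
  # class-mean / nearest-centroid max-margin direction for the balanced
  # 4-sample training sets this scheme produces), bias at the midpoint.
  mu0 <- colMeans(train_x[train_y == 0, , drop = FALSE])
  mu1 <- colMeans(train_x[train_y == 1, , drop = FALSE])
  w <- mu1 - mu0
  b <- sum(w * (mu0 + mu1) / 2)
  as.integer(drop(test_x %*% w) - b > 0)
}

#' Pseudo-trial bootstrap leave-one-out decoding
#'
#' For each left-out trial and bootstrap repeat, the remaining trials of
#' each class are randomly partitioned into `n_folds` folds which are
#' averaged into pseudo-trials; two pseudo-trials per class (the pair
#' rotates across repeats) form the training set of a linear
#' classifier, which is then applied to the left-out trial. Accuracy per
#' trial is the fraction of correct classifications over `n_boot`
#' repeats, computed independently at every time point. The left-out
#' trial never contributes to any pseudo-trial: within a repeat, folds
#' are drawn over all trials of a class and the left-out trial is
#' removed from its fold by exact mean subtraction. To keep both
#' classes' pseudo-trials at identical averaging depth (an asymmetry
#' here biases nearest-mean classification below chance), one randomly
#' chosen trial of the opposite class is excluded the same way.
#'
#' @param patterns numeric array trial x feature x time (a trial x
#'   feature matrix is treated as one time point).
#' @param labels binary class labels (two levels).
#' @param n_boot bootstrap repeats.
#' @param n_folds folds for pseudo-trial averaging.
#' @param seed integer seed.
#' @param max_imbalance tolerated class-count ratio before stratified
#'   subsampling of the majority class (with a message).
#' @return a `maat_decoding` list: `accuracy` (trial x time, in [0,1]),
#'   `labels`, `n_boot`, `n_folds`, `time_index`.
#' @export
pseudo_trial_decode <- function(patterns, labels, n_boot = 100,
                                n_folds = 3, seed, max_imbalance = 1.5) {
  if (missing(seed)) stop("seed must be given")
  if (length(dim(patterns)) == 2) {
    patterns <- array(patterns, dim = c(dim(patterns), 1))
  }
  stopifnot(length(dim(patterns)) == 3,
            dim(patterns)[1] == length(labels))
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("exactly two classes required")
  y <- as.integer(labels == lv[2])
  n_all <- length(y)
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  if (min(length(idx0), length(idx1)) < n_folds * 2 + 1) {
    stop("need >= ", n_folds * 2 + 1, " trials per class")
  }
  set.seed(split_seed(seed, "decode"))
  ratio <- max(length(idx0), length(idx1)) /
    min(length(idx0), length(idx1))
  active <- seq_len(n_all)
  if (ratio > max_imbalance) {
    message("class imbalance ", round(ratio, 2),
            ": stratified subsampling of the majority class")
    n_min <- min(length(idx0), length(idx1))
    keep0 <- if (length(idx0) > n_min) sample(idx0, n_min) else idx0
    keep1 <- if (length(idx1) > n_min) sample(idx1, n_min) else idx1
    active <- sort(c(keep0, keep1))
  }
  n_time <- dim(patterns)[3]
  acc <- matrix(NA_real_, n_all, n_time)
  cls_idx <- list(intersect(idx0, active), intersect(idx1, active))
  for (ti in seq_len(n_time)) {
    X <- patterns[, , ti, drop = FALSE][, , 1]
    hits <- numeric(n_all); tries <- numeric(n_all)
    for (b in seq_len(n_boot)) {
      # one random fold partition per class per repeat
      folds <- lapply(cls_idx, function(ix) {
        split(sample(ix), rep(seq_len(n_folds),
                              length.out = length(ix)))
      })
      fsums <- lapply(folds, function(fl) {
        t(vapply(fl, function(ix) colSums(X[ix, , drop = FALSE]),
                 numeric(ncol(X))))
      })
      fns <- lapply(folds, function(fl) lengths(fl))
      drop_fold <- (b - 1) %% n_folds + 1 # rotating excluded pseudo-trial
      for (i in active) {
        ci <- y[i] + 1
        oc <- 3 - ci
        inf <- which(vapply(folds[[ci]],
                            function(ix) i %in% ix, logical(1)))
        # matched exclusion from the opposite class (balance averaging)
        j <- cls_idx[[oc]][sample.int(length(cls_idx[[oc]]), 1)]
        jnf <- which(vapply(folds[[oc]],
                            function(ix) j %in% ix, logical(1)))
        means <- vector("list", 2)
        for (cc in 1:2) {
          s <- fsums[[cc]]; nn <- fns[[cc]]
          if (cc == ci) { # remove left-out trial from its fold
            s[inf, ] <- s[inf, ] - X[i, ]
            nn[inf] <- nn[inf] - 1
          } else {        # remove the matched exclusion from its fold
            s[jnf, ] <- s[jnf, ] - X[j, ]
            nn[jnf] <- nn[jnf] - 1
          }
          if (any(nn == 0)) { means <- NULL; break }
          means[[cc]] <- s / nn
        }
        if (is.null(means)) next
        use <- setdiff(seq_len(n_folds), drop_fold)[1:2]
        train_x <- rbind(means[[1]][use, , drop = FALSE],
                         means[[2]][use, , drop = FALSE])
        train_y <- rep(c(0L, 1L), each = 2)
        pred <- lda_ridge_classify(train_x, train_y,
                                   matrix(X[i, ], nrow = 1))
        hits[i] <- hits[i] + as.integer(pred == y[i])
        tries[i] <- tries[i] + 1
      }
    }
    acc[active, ti] <- hits[active] / pmax(tries[active], 1)
  }
  structure(list(accuracy = acc, labels = labels, n_boot = n_boot,
                 n_folds = n_folds, classes = lv,
                 active = active),
            class = "maat_decoding")
}

#' Condition-wise decoding accuracy curves and load summaries
#'
#' Averages per-trial bootstrapped accuracies over trials within each
#' level of a condition assignment, and (when the assignment is target
#' load) summarizes each subject's linear load effect for group models.
#' Empty condition cells are flagged missing rather than dropped
#' silently.
#'
#' @param result a `maat_decoding`.
#' @param assignment per-trial condition labels (e.g. cued/uncued,
#'   probed/unprobed, or load 1-4).
#' @return list: `curves` (condition x time mean accuracy), `n_trials`
#'   per condition, `missing` (conditions with no trials), and, when
#'   `assignment` is numeric, `load_slope` (OLS slope of condition mean
#'   accuracy on load).
#' @export
condition_decoding_curves <- function(result, assignment) {
  stopifnot(inherits(result, "maat_decoding"),
            length(assignment) == nrow(result$accuracy))
  lev <- sort(unique(assignment))
  nt <- ncol(result$accuracy)
  curves <- matrix(NA_real_, length(lev), nt,
                   dimnames = list(as.character(lev), NULL))
  for (k in seq_along(lev)) {
    rows <- intersect(which(assignment == lev[k]), result$active)
    if (length(rows)) {
      curves[k, ] <- colMeans(result$accuracy[rows, , drop = FALSE],
                              na.rm = TRUE)
    }
  }
  n_tr <- vapply(lev, function(l)
    length(intersect(which(assignment == l), result$active)), numeric(1))
  out <- list(curves = curves, n_trials = n_tr,
              missing = lev[n_tr == 0])
  if (is.numeric(assignment) && length(lev) >= 2) {
    mean_acc <- rowMeans(curves)
    ok <- is.finite(mean_acc)
    if (sum(ok) >= 2) {
      out$load_slope <- unname(ols_fit(as.numeric(lev[ok]),
                                       mean_acc[ok])["slope"])
    }
  }
  out
}
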