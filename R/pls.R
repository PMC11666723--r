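## Task and behavioral partial least squares with permutation and
## bootstrap-ratio inference.

fix_sign <- function(U, V) {
  # deterministic sign convention: each V column's largest-magnitude
  # element is positive
  for (j in seq_len(ncol(V))) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  list(U = U, V = V)
}

pls_svd <- function(M) {
  s <- svd(M)
  fs <- fix_sign(s$u, s$v)
  list(U = fs$U, S = s$d, V = fs$V)
}

task_pls_matrix <- function(X, subject, group, condition,
                            remove_group_means = TRUE) {
  glev <- unique(group)
  clev <- sort(unique(condition))
  blocks <- lapply(glev, function(g) {
    rows <- matrix(NA_real_, length(clev), ncol(X))
    for (k in seq_along(clev)) {
      sel <- group == g & condition == clev[k]
      rows[k, ] <- colMeans(X[sel, , drop = FALSE])
    }
    if (remove_group_means) {
      rows <- sweep(rows, 2, colMeans(rows))
    }
    rows
  })
  M <- do.call(rbind, blocks)
  rownames(M) <- paste(rep(glev, each = length(clev)),
                       rep(clev, length(glev)), sep = ":")
  M
}

#' Task partial least squares
#'
#' Decomposes the group-wise condition-mean matrix of a neural data
#' block by SVD into latent variables relating experimental conditions
#' to neural patterns. With `remove_group_means = TRUE` each group's
#' mean across conditions is removed first, so latent variables express
#' condition and condition-by-group effects. Brainscores project every
#' subject-condition row onto the neural saliences.
#'
#' @param X numeric matrix, subject-condition rows x neural columns.
#' @param subject,group,condition row metadata vectors.
#' @param remove_group_means see above.
#' @return a `maat_pls` object: `U` (condition saliences, rows ordered
#'   group x condition), `S` (singular values, descending), `V` (neural
#'   saliences, column-orthonormal, sign-fixed), `brainscores`
#'   (subject-condition x LV), row metadata, and bookkeeping needed by
#'   [pls_permutation()] / [pls_bootstrap()].
#' @export
task_pls <- function(X, subject, group = rep("all", nrow(X)), condition,
                     remove_group_means = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(subject), length(group) == nrow(X),
            length(condition) == nrow(X))
  if (length(unique(condition)) < 2) stop("need >= 2 conditions")
  for (g in unique(group)) {
    if (length(unique(subject[group == g])) < 2)
      stop("need >= 2 subjects per group")
  }
  if (anyNA(X)) stop("missing cells in the data matrix")
  M <- task_pls_matrix(X, subject, group, condition, remove_group_means)
  dec <- pls_svd(M)
  bs <- X %*% dec$V
  structure(list(type = "task", U = dec$U, S = dec$S, V = dec$V,
                 brainscores = bs, M = M, X = X,
                 subject = subject, group = group, condition = condition,
                 remove_group_means = remove_group_means),
            class = "maat_pls")
}

behavioral_pls_matrix <- function(Y, B, group) {
  glev <- unique(group)
  blocks <- lapply(glev, function(g) {
    sel <- group == g
    stats::cor(B[sel, , drop = FALSE], Y[sel, , drop = FALSE])
  })
  do.call(rbind, blocks)
}

#' Behavioral partial least squares
#'
#' Decomposes the (within-group stacked) between-subject correlation
#' matrix between a behavior block and a neural block. Behavioral
#' saliences land in `U`, neural saliences in `V`; brainscores are the
#' neural rows projected on `V`.
#'
#' @param Y neural matrix, subject x variable.
#' @param B behavior matrix, subject x variable (>= 2 columns; columns
#'   must have nonzero variance).
#' @param group optional per-subject group labels (correlations are
#'   computed within group and stacked).
#' @return a `maat_pls` object (see [task_pls()]).
#' @export
behavioral_pls <- function(Y, B, group = rep("all", nrow(Y))) {
  Y <- as.matrix(Y); B <- as.matrix(B)
  stopifnot(nrow(Y) == nrow(B), nrow(Y) == length(group))
  if (ncol(B) < 2) stop("need >= 2 behavioral variables")
  zv <- which(apply(B, 2, sd) == 0)
  if (length(zv)) stop("zero-variance behavioral column: ",
                       paste(colnames(B)[zv] %||% zv, collapse = ", "))
  zvy <- which(apply(Y, 2, sd) == 0)
  if (length(zvy)) stop("zero-variance neural column: ",
                        paste(colnames(Y)[zvy] %||% zvy, collapse = ", "))
  R <- behavioral_pls_matrix(Y, B, group)
  dec <- pls_svd(R)
  bs <- Y %*% dec$V
  structure(list(type = "behavioral", U = dec$U, S = dec$S, V = dec$V,
                 brainscores = bs, M = R, X = Y, B = B,
                 group = group),
            class = "maat_pls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.maat_pls <- function(x, ...) {
  cat(sprintf("<maat_pls:%s> %d LVs, singular values: %s\n", x$type,
              length(x$S), paste(signif(x$S, 4), collapse = ", ")))
  if (!is.null(x$perm_p)) cat("  permutation p:",
                              paste(signif(x$perm_p, 3), collapse = ", "),
                              "\n")
  invisible(x)
}

#' Permutation test of PLS singular values
#'
#' Re-decomposes the model under the exchangeability null: for task PLS
#' the condition labels are permuted within subject; for behavioral PLS
#' the subject rows of the behavior block are shuffled (within group),
#' leaving neural structure intact. Latent variables correspond across
#' permutations by singular-value rank. `p` is the fraction of permuted
#' singular values at or above the observed one.
#'
#' @param model a `maat_pls`.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return the model with `perm_p` (per LV) and `perm_S` attached.
#' @export
pls_permutation <- function(model, n_perm = 1000, seed) {
  stopifnot(inherits(model, "maat_pls"))
  if (missing(seed)) stop("seed must be given")
  set.seed(split_seed(seed, "pls_perm"))
  k <- length(model$S)
  Sp <- matrix(NA_real_, n_perm, k)
  if (model$type == "task") {
    for (p in seq_len(n_perm)) {
      cond_p <- model$condition
      for (s in unique(model$subject)) {
        ix <- which(model$subject == s)
        cond_p[ix] <- sample(model$condition[ix])
      }
      M <- task_pls_matrix(model$X, model$subject, model$group, cond_p,
                           model$remove_group_means)
      Sp[p, ] <- svd(M, nu = 0, nv = 0)$d[seq_len(k)]
    }
  } else {
    for (p in seq_len(n_perm)) {
      ord <- seq_len(nrow(model$B))
      for (g in unique(model$group)) {
        ix <- which(model$group == g)
        ord[ix] <- sample(ix)
      }
      R <- behavioral_pls_matrix(model$X, model$B[ord, , drop = FALSE],
                                 model$group)
      Sp[p, ] <- svd(R, nu = 0, nv = 0)$d[seq_len(k)]
    }
  }
  model$perm_S <- Sp
  model$perm_p <- vapply(seq_len(k), function(j) {
    mean(Sp[, j] >= model$S[j])
  }, numeric(1))
  model
}

procrustes_align <- function(Vb, V) {
  # orthogonal rotation of the resampled saliences onto the originals
  s <- svd(crossprod(Vb, V))
  Q <- s$u %*% t(s$v)
  Vb %*% Q
}

#' Bootstrap ratios for PLS neural saliences
#'
#' Resamples subjects with replacement (stratified within group),
#' re-decomposes, aligns each resampled salience matrix to the original
#' by orthogonal Procrustes rotation (removing sign/rotation
#' indeterminacy), and divides the original saliences by the bootstrap
#' standard error. `|BSR| >= threshold` marks reliable variables
#' (threshold 3 ~ a 99.9% normal interval). Degenerate resamples (a
#' zero-variance column, fewer than 2 distinct subjects in a group) are
#' redrawn and counted.
#'
#' @param model a `maat_pls`.
#' @param n_boot bootstrap resamples (> 0).
#' @param threshold BSR reliability threshold.
#' @param seed integer seed.
#' @return the model with `bsr` (variables x LV), `bsr_se`,
#'   `reliable` (logical `|bsr| >= threshold`), `n_redrawn` attached.
#' @export
pls_bootstrap <- function(model, n_boot = 1000, threshold = 3, seed) {
  stopifnot(inherits(model, "maat_pls"))
  if (n_boot <= 0) stop("n_boot must be positive")
  if (missing(seed)) stop("seed must be given")
  set.seed(split_seed(seed, "pls_boot"))
  k <- length(model$S)
  nv <- nrow(model$V)
  Vb <- array(NA_real_, dim = c(nv, k, n_boot))
  redrawn <- 0
  subj_of <- if (model$type == "task") model$subject
             else seq_len(nrow(model$X))
  grp_of <- model$group
  subj_tab <- unique(data.frame(subject = subj_of, group = grp_of,
                                stringsAsFactors = FALSE))
  for (b in seq_len(n_boot)) {
    for (attempt in 1:50) {
      pick <- unlist(lapply(unique(subj_tab$group), function(g) {
        pool <- subj_tab$subject[subj_tab$group == g]
        sample(pool, length(pool), replace = TRUE)
      }))
      rows <- unlist(lapply(pick, function(s) which(subj_of == s)))
      ok <- TRUE
      if (model$type == "task") {
        M <- try(task_pls_matrix(model$X[rows, , drop = FALSE],
                                 NULL, grp_of[rows],
                                 model$condition[rows],
                                 model$remove_group_means), silent = TRUE)
        if (inherits(M, "try-error") || anyNA(M)) ok <- FALSE
      } else {
        Yb <- model$X[rows, , drop = FALSE]
        Bb <- model$B[rows, , drop = FALSE]
        if (any(apply(Bb, 2, sd) == 0) || any(apply(Yb, 2, sd) == 0)) {
          ok <- FALSE
        } else {
          M <- behavioral_pls_matrix(Yb, Bb, grp_of[rows])
        }
      }
      if (ok) break
      redrawn <- redrawn + 1
    }
    if (!ok) stop("could not draw a non-degenerate bootstrap resample")
    sv <- svd(M)
    Vb[, , b] <- procrustes_align(sv$v[, seq_len(k), drop = FALSE],
                                  model$V)
  }
  se <- apply(Vb, c(1, 2), sd)
  se[se < 1e-12] <- NA_real_
  bsr <- model$V / se
  model$bsr <- bsr
  model$bsr_se <- se
  model$reliable <- !is.na(bsr) & abs(bsr) >= threshold
  model$bsr_threshold <- threshold
  model$n_redrawn <- redrawn
  model
}
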