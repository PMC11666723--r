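test_that("load slopes equal closed-form OLS on every input", {
  t1 <- data.frame(subject = "a", load = 1:4, value = c(2, 4, 6, 8))
  r1 <- linear_load_slope(t1)
  expect_equal(r1$slopes$beta, 2)
  expect_equal(r1$slopes$intercept, 0)
  t2 <- data.frame(subject = "a", load = 1:4, value = rep(3.3, 4))
  expect_equal(linear_load_slope(t2)$slopes$beta, 0)
  # random tables match the normal-equation oracle (lm)
  set.seed(1)
  for (i in 1:5) {
    tr <- data.frame(subject = rep(c("a", "b"), each = 4),
                     group = rep(c("young", "old"), each = 4),
                     load = rep(1:4, 2), value = rnorm(8))
    rs <- linear_load_slope(tr)$slopes
    for (s in c("a", "b")) {
      ref <- coef(lm(value ~ load, tr[tr$subject == s, ]))
      expect_equal(rs$beta[rs$subject == s], unname(ref[2]),
                   tolerance = 1e-10)
    }
  }
  expect_error(linear_load_slope(
    data.frame(subject = "a", load = c(2, 2), value = 1:2)), "single")
})

test_that("group t-tests accompany the slopes", {
  set.seed(2)
  tab <- data.frame(subject = rep(sprintf("s%d", 1:10), each = 4),
                    group = rep(c("young", "old"), each = 20),
                    load = rep(1:4, 10))
  tab$value <- -0.3 * tab$load * (tab$group == "young") + rnorm(40, 0, 0.1)
  r <- linear_load_slope(tab)
  expect_lt(r$within_group$young$p.value, 0.01)
  expect_lt(r$between_group$p.value, 0.01)
})

test_that("MAD winsorization clips to the k-scaled-MAD bound", {
  # hand computation: median 3, scaled MAD 1.4826, bound 3 + 3*1.4826
  x <- c(1, 2, 3, 4, 100)
  w <- mad_winsorize(x)
  expect_equal(w$values[5], 3 + 3 * 1.4826, tolerance = 1e-10)
  expect_identical(w$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # no value beyond bounds -> identity
  y <- c(4, 5, 6, 7)
  expect_identical(mad_winsorize(y)$values, y)
  # all equal: degenerate only when spread exists elsewhere
  z <- rep(2, 6)
  wz <- mad_winsorize(z)
  expect_false(any(wz$outlier))
  expect_false(wz$degenerate[["all"]])
  zz <- c(rep(2, 5), 9)
  expect_true(mad_winsorize(zz)$degenerate[["all"]])
  # idempotence
  w2 <- mad_winsorize(w$values)
  expect_equal(w2$values, w$values, tolerance = 1e-12)
  expect_error(mad_winsorize(1:3), ">= 4")
})

test_that("within-subject centering preserves condition means exactly", {
  tab <- data.frame(subject = rep(c("A", "B"), each = 2),
                    condition = rep(c("c1", "c2"), 2),
                    value = c(1, 3, 5, 7))
  out <- within_subject_center(tab)
  expect_equal(out$value, c(3, 5, 3, 5))
  cm_in <- tapply(tab$value, tab$condition, mean)
  cm_out <- tapply(out$value, out$condition, mean)
  expect_equal(cm_out, cm_in)
  # single subject: unchanged
  one <- tab[tab$subject == "A", ]
  expect_equal(within_subject_center(one)$value, one$value)
  # shift invariance: adding a constant to one subject leaves the
  # centered deviation pattern untouched (the restored grand mean
  # absorbs c/n by construction)
  tab2 <- tab
  tab2$value[tab2$subject == "B"] <- tab2$value[tab2$subject == "B"] + 11
  v2 <- within_subject_center(tab2)$value
  expect_equal(v2 - mean(v2), out$value - mean(out$value))
  expect_error(within_subject_center(tab[-1, ]), "incomplete")
})

test_that("temporal clusters detect planted windows and respect masses", {
  set.seed(3)
  n_sub <- 16; n_pt <- 40
  dat <- matrix(rnorm(n_sub * n_pt), n_sub)
  dat[, 15:24] <- dat[, 15:24] + 1.6 # 10-point contiguous plant
  ct <- cluster_permutation_test(dat, n_perm = 300, seed = 4)
  expect_gt(length(ct$clusters), 0)
  sig <- Filter(function(cl) cl$significant, ct$clusters)
  expect_gt(length(sig), 0)
  covered <- intersect(sig[[which.max(vapply(sig, function(cl)
    abs(cl$mass), numeric(1)))]]$members, 15:24)
  expect_gte(length(covered), 8) # >= 80% of the planted window
  # cluster p bounded below by 1/(n_perm + 1)
  ps <- vapply(ct$clusters, function(cl) cl$p, numeric(1))
  expect_true(all(ps >= 1 / 301 - 1e-12 & ps <= 1))
})

test_that("spatial clusters require three neighboring channels", {
  set.seed(5)
  channels <- c("A", "B", "C", "D", "E")
  neighbors <- list(A = "B", B = c("A", "C"), C = c("B", "D"),
                    D = c("C", "E"), E = "D")
  n_sub <- 14; n_time <- 8
  grid <- expand.grid(ch = 1:5, t = 1:n_time)
  mk <- function(effect_ch) {
    dat <- matrix(rnorm(n_sub * nrow(grid), 0, 0.5), n_sub)
    for (ch in effect_ch) {
      dat[, grid$ch == ch & grid$t %in% 3:6] <-
        dat[, grid$ch == ch & grid$t %in% 3:6] + 3
    }
    dat
  }
  run <- function(dat) cluster_permutation_test(
    dat, neighbors = neighbors, channel_of = grid$ch, time_of = grid$t,
    channels = channels, n_perm = 200, seed = 6)
  # effect on only 2 (isolated) channels: min-3 rule blocks the cluster
  ct2 <- run(mk(c(1, 5)))
  expect_equal(length(ct2$clusters), 0)
  # effect on 3 neighboring channels: cluster forms
  ct3 <- run(mk(2:4))
  expect_gt(length(ct3$clusters), 0)
  expect_true(any(vapply(ct3$clusters, function(cl) cl$significant,
                         logical(1))))
})

test_that("null cluster tests keep family-wise error near nominal", {
  # scaled-down null calibration (the 200-replicate version runs in the
  # acceptance suite)
  set.seed(7)
  fwer <- mean(vapply(1:60, function(i) {
    dat <- matrix(rnorm(12 * 25), 12)
    ct <- cluster_permutation_test(dat, n_perm = 150, seed = 700 + i)
    any(vapply(ct$clusters, function(cl) cl$significant, logical(1)))
  }, logical(1)))
  expect_lte(fwer, 0.1)
})

test_that("random-intercept models recover planted fixed effects", {
  set.seed(8)
  gen <- function(seed) {
    set.seed(seed)
    n_sub <- 24
    tab <- expand.grid(subject = sprintf("s%02d", 1:n_sub), load = 1:4)
    tab$group <- ifelse(as.integer(sub("s", "", tab$subject)) <= 12,
                        "old", "young")
    u <- rnorm(n_sub, 0, 0.3)
    tab$value <- -0.18 * tab$load - 0.862 * (tab$group == "old") +
      u[as.integer(sub("s", "", tab$subject))] + rnorm(nrow(tab), 0, 0.3)
    tab
  }
  signs_ok <- vapply(1:20, function(i) {
    r <- random_intercept_model(gen(100 + i))
    est <- r$fixed$estimate
    names(est) <- r$fixed$term
    est["load"] < 0 && est[grep("group", names(est))[1]] > 0
    # groupyoung > 0 equals old effect -0.862 (old is reference-coded
    # alphabetically first), so the sign check is on the young contrast
  }, logical(1))
  expect_gte(mean(signs_ok), 0.95)
  # interaction dropped when truly absent
  r <- random_intercept_model(gen(1))
  expect_false(r$interaction_kept)
  # balanced two-stage vs mixed-model load estimates agree
  tab <- gen(2)
  r2 <- random_intercept_model(tab)
  ls <- linear_load_slope(data.frame(tab, check.names = FALSE))
  expect_equal(r2$fixed$estimate[r2$fixed$term == "load"],
               mean(ls$slopes$beta), tolerance = 1e-6)
})
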