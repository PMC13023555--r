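test_that("age adjustment recovers exact coefficients on noiseless data", {
  set.seed(51)
  n <- 200
  age <- runif(n, 40, 75)
  group <- rep(0:1, each = n / 2)
  # known slope 0.5/yr, group offset 3, interaction 0.2
  y <- 10 + 0.5 * (age - mean(age)) + 3 * group +
    0.2 * (age - mean(age)) * group
  m <- fit_age_adjustment(cbind(feat = y), age, group)
  expect_equal(unname(m$coef["age", 1]), 0.5, tolerance = 1e-10)
  expect_equal(unname(m$coef["age_group", 1]), 0.2, tolerance = 1e-10)
  adj <- apply_age_adjustment(m, cbind(feat = y), age, group)
  # within-group age dependence is removed by construction (the noiseless
  # adjusted feature is exactly constant, so test the covariance)
  expect_lt(abs(cov(adj[group == 0, 1], age[group == 0])), 1e-10)
  expect_lt(abs(cov(adj[group == 1, 1], age[group == 1])), 1e-10)
  # group offset survives
  expect_equal(mean(adj[group == 1, 1]) - mean(adj[group == 0, 1]), 3,
               tolerance = 1e-10)
})

test_that("adjustment coefficients match a hand-built normal-equations solve", {
  age <- c(45, 50, 55, 60, 65, 70)
  group <- c(0, 0, 0, 1, 1, 1)
  y <- c(3.1, 2.9, 3.4, 4.0, 4.4, 4.1)
  D <- cbind(1, age - mean(age), group, (age - mean(age)) * group)
  beta <- solve(t(D) %*% D, t(D) %*% y)
  m <- fit_age_adjustment(cbind(y = y), age, group)
  expect_equal(unname(m$coef[, 1]), unname(drop(beta)), tolerance = 1e-10)
})

test_that("adjustment is a no-op at the training mean age and idempotent in slope", {
  set.seed(52)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  age <- runif(20, 40, 75)
  group <- rep(0:1, 10)
  m <- fit_age_adjustment(X, age, group)
  same_age <- rep(m$age_mean, 20)
  expect_equal(apply_age_adjustment(m, X, same_age, group), X)
  # refitting on adjusted training data leaves no age slope
  adj <- apply_age_adjustment(m, X, age, group)
  m2 <- fit_age_adjustment(adj, age, group)
  expect_lt(max(abs(m2$coef[c("age", "age_group"), ])), 1e-10)
})

test_that("beta_age = 0 generators pass through the adjustment", {
  set.seed(53)
  X <- cbind(f = rnorm(100))
  age <- runif(100, 40, 75)
  group <- rep(0:1, 50)
  m <- fit_age_adjustment(X, age, group)
  adj <- apply_age_adjustment(m, X, age, group)
  # OLS slope on pure noise is O(sd/sqrt(n)); the correction is small
  expect_lt(max(abs(adj - X)), 1.5)
  expect_gt(cor(adj[, 1], X[, 1]), 0.98)
})

test_that("adjustment rejects degenerate designs", {
  expect_error(fit_age_adjustment(cbind(1:4), c(50, 50, 60, 60), rep(0, 4)),
               "both groups")
  expect_error(fit_age_adjustment(cbind(1:3), c(50, 55, 60), c(0, 1, 1)),
               "at least 4")
  expect_error(fit_age_adjustment(cbind(1:4), rep(55, 4), c(0, 0, 1, 1)),
               "rank-deficient")
})

test_that("Cliff's delta equals exhaustive pair counting", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- mann_whitney_cliffs(x, y)
  wins <- losses <- 0
  for (a in x) for (b in y) {
    wins <- wins + (a > b); losses <- losses + (a < b)
  }
  expect_equal(res$delta, (wins - losses) / 9)
  expect_equal(res$U, pair_win_count(x, y))
  # identical samples: delta 0; complete dominance: delta 1
  z <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(mann_whitney_cliffs(z, z)$delta, 0)
  expect_equal(mann_whitney_cliffs(z + 10, z)$delta, 1)
})

test_that("Mann-Whitney p-values track the reference implementation", {
  set.seed(54)
  x <- rnorm(15); y <- rnorm(18, 0.8)
  expect_equal(mann_whitney_cliffs(x, y)$p, wilcox.test(x, y)$p.value)
  xl <- rnorm(30); yl <- rnorm(25, 0.3)
  expect_equal(mann_whitney_cliffs(xl, yl)$p,
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value)
})

test_that("BH adjustment follows the hand-applied step-up recursion", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up by hand: p_(i) * m / i, then cumulative minima from the top
  raw <- p * 4 / 1:4
  hand <- rev(cummin(rev(raw)))
  expect_equal(bh_fdr(p), hand)
  expect_equal(hand, rep(0.04, 4))
  # order-preserving under permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm]), hand[perm])
  expect_true(all(bh_fdr(p) >= p))
})

test_that("univariate battery returns one adjusted row per feature", {
  set.seed(55)
  ch <- generate_null_cohort(cohort_config(n_hs = 10, n_oa = 10), seed = 5)
  ft <- cohort_true_features(ch)
  ub <- univariate_battery(ft)
  expect_equal(nrow(ub), 18L)
  expect_true(all(ub$p_adj >= ub$p))
  expect_true(all(abs(ub$delta) <= 1))
})

test_that("permutation MANOVA attains its minimum p on separated groups", {
  scores <- c(rnorm(12, -5, 0.1), rnorm(12, 5, 0.1))
  labels <- rep(0:1, each = 12)
  res <- np_manova(scores, labels, n_perm = 999, seed = 6)
  expect_equal(res$p, 1 / 1000)
  # affine invariance of the eigenvalue statistic
  res2 <- np_manova(3.7 * scores - 11, labels, n_perm = 99, seed = 6)
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-10)
  expect_error(np_manova(rep(1, 24), labels, 99), "constant")
})

test_that("permutation MANOVA is calibrated under the null", {
  set.seed(57)
  rej <- 0; reps <- 150
  for (i in seq_len(reps)) {
    scores <- rnorm(24)
    p <- np_manova(scores, rep(0:1, 12), n_perm = 99, seed = i)$p
    rej <- rej + (p <= 0.05)
  }
  expect_gte(rej / reps, 0.01)
  expect_lte(rej / reps, 0.10)
})

test_that("AUC equals the normalized Mann-Whitney U across modules", {
  set.seed(58)
  for (i in 1:10) {
    x <- sample(rnorm(12), replace = TRUE)  # ties included
    y <- sample(rnorm(15), replace = TRUE)
    auc <- roc_auc(c(x, y), rep(c(1, 0), c(12, 15)))$auc
    U <- mann_whitney_cliffs(x, y)$U
    expect_lt(abs(auc * 12 * 15 - U), 1e-9)
  }
})
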