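test_that("ROC/AUC handles separation, ties and brute-force counting", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), rep(0:1, each = 3))$auc, 1)
  expect_equal(roc_auc(rep(5, 6), rep(0:1, each = 3))$auc, 0.5)
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  labels <- c(0, 0, 1, 1, 0, 1)
  want <- pair_win_count(scores[labels == 1], scores[labels == 0]) / 9
  expect_equal(roc_auc(scores, labels)$auc, want)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  curve <- roc_auc(scores, labels)$curve
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})

test_that("bootstrap CI collapses under perfect separation and is reproducible", {
  scores <- c(1:5, 11:15); labels <- rep(0:1, each = 5)
  ci <- bootstrap_auc_ci(scores, labels, B = 200, seed = 4)
  expect_equal(ci$ci, c(1, 1))
  s <- rnorm(20)
  a <- bootstrap_auc_ci(s, rep(0:1, 10), B = 100, seed = 5)
  b <- bootstrap_auc_ci(s, rep(0:1, 10), B = 100, seed = 5)
  expect_identical(a$boot, b$boot)
})

test_that("the bootstrap interval almost always contains the point AUC", {
  set.seed(81)
  hits <- 0
  for (i in 1:10) {
    scores <- c(rnorm(13), rnorm(13, 0.8))
    labels <- rep(0:1, each = 13)
    ci <- bootstrap_auc_ci(scores, labels, B = 300, seed = i)
    hits <- hits + (ci$auc >= ci$ci[1] && ci$auc <= ci$ci[2])
  }
  expect_gte(hits, 9)
})

test_that("DeLong test matches the reference implementation and is antisymmetric", {
  set.seed(82)
  labels <- rep(0:1, each = 5)
  sa <- rnorm(10) + labels
  sb <- rnorm(10) + 0.5 * labels
  res <- delong_test(sa, sb, labels)
  ref <- pROC::roc.test(pROC::roc(labels, sa, quiet = TRUE),
                        pROC::roc(labels, sb, quiet = TRUE),
                        method = "delong")
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$auc_a - res$auc_b, ref$estimate[[1]] - ref$estimate[[2]],
               tolerance = 1e-12)
  swapped <- delong_test(sb, sa, labels)
  expect_equal(swapped$diff, -res$diff)
  expect_equal(swapped$p, res$p)
  same <- delong_test(sa, sa, labels)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
})

test_that("calibration and Brier score match hand computation", {
  expect_equal(calibration_brier(c(0, 0, 1, 1), c(0, 0, 1, 1))$brier, 0)
  expect_equal(calibration_brier(rep(0.5, 8), rep(0:1, 4))$brier, 0.25)
  post <- c(0.1, 0.3, 0.6, 0.9); lab <- c(0, 1, 0, 1)
  cb <- calibration_brier(post, lab, n_bins = 2)
  expect_equal(cb$brier, mean((post - lab)^2))
  expect_equal(cb$curve$mean_pred, c(0.2, 0.75))
  expect_equal(cb$curve$obs_frac, c(0.5, 0.5))
  expect_equal(cb$curve$n, c(2L, 2L))
})

test_that("decision curves obey their closed forms", {
  post <- c(0.2, 0.9, 0.8, 0.1); lab <- c(0, 1, 1, 0)
  dc <- decision_curve(post, lab, thresholds = c(0.3, 0.5, 0.7))
  expect_equal(dc$nb_none, rep(0, 3))
  # treat-all at pt = prevalence = 0.5 nets zero
  expect_equal(dc$nb_all[dc$threshold == 0.5], 0)
  # a perfect classifier nets the prevalence at every threshold
  expect_equal(dc$nb_model, rep(0.5, 3))
})

test_that("weight stability separates informative from noise features", {
  set.seed(83)
  cfg <- cv_config(outer = 3, inner = 3, repeats = 4,
                   lambda_grid = c(0.1, 1))
  top1 <- 0
  for (i in 1:10) {
    d <- toy_features(26, p = 6, shift_cols = 1, shift = 2, seed = 830 + i)
    res <- nested_cv(d$X, d$y, config = cfg, seed = i)
    ws <- weight_stability(res$weights)
    top1 <- top1 + (ws$feature[1] == "f1")
  }
  expect_gte(top1, 9)
  # constant fold-weights have zero variance and infinite stability
  W <- matrix(rep(c(2, 0.5), each = 4), 4, 2,
              dimnames = list(NULL, c("a", "b")))
  ws <- weight_stability(W)
  expect_equal(ws$variance, c(0, 0))
  expect_true(all(is.infinite(ws$stability)))
})

test_that("pure-noise fold weights show near-chance sign consistency", {
  set.seed(84)
  cfg <- cv_config(outer = 4, inner = 3, repeats = 5,
                   lambda_grid = c(0.1, 1))
  d <- toy_features(20, p = 8, seed = 85)
  res <- nested_cv(d$X, d$y, config = cfg, seed = 11)
  sign_consistency <- apply(res$weights, 2, function(w) {
    max(mean(w > 0), mean(w < 0))
  })
  expect_lt(mean(sign_consistency), 0.9)
})

test_that("weight-stability permutation p-values are valid and ordered", {
  d <- toy_features(13, p = 4, shift_cols = 1, shift = 2.5, seed = 86)
  cfg <- cv_config(outer = 3, inner = 3, repeats = 1,
                   lambda_grid = c(0.1, 1))
  res <- nested_cv(d$X, d$y, config = cfg, seed = 2)
  ws <- weight_stability(res$weights, X = d$X, y = d$y, config = cfg,
                         n_perm = 19, seed = 3)
  expect_true(all(ws$p >= 1 / 20 & ws$p <= 1))
  expect_true(all(ws$p_adj >= ws$p))
  expect_equal(ws$rank, seq_len(4))
})
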