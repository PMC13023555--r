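## Nested cross-validation for the regularized LDA: outer folds estimate
## performance, inner folds select the shrinkage, and all preprocessing (age
## adjustment, standardization) is refit on the training side of every split.

#' Cross-validation configuration
#'
#' @param outer,inner stratified fold counts for the outer (performance) and
#'   inner (shrinkage selection) loops.
#' @param repeats number of repetitions with reshuffled folds; the headline
#'   AUC is the mean of the per-repeat pooled out-of-fold AUCs.
#' @param lambda_grid candidate shrinkage intensities; ties in inner AUC are
#'   broken toward the larger (more stable) lambda.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(outer = 5L, inner = 5L, repeats = 20L,
                      lambda_grid = c(0, 0.01, 0.1, 0.3, 0.5, 0.7, 0.9, 1.0)) {
  structure(list(outer = as.integer(outer), inner = as.integer(inner),
                 repeats = as.integer(repeats),
                 lambda_grid = sort(as.numeric(lambda_grid))),
            class = "cv_config")
}

## fold labels 1..k, stratified by class, from the current RNG stream
.stratified_folds <- function(y, k) {
  if (min(table(y)) < k) stop("a fold would lack a class: too many folds")
  folds <- integer(length(y))
  for (g in unique(y)) {
    idx <- sample(which(y == g))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

## sufficient statistics + per-lambda weights, shared by the inner loop
.lda_suff <- function(X, y) {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  c0 <- sweep(X[y == 0, , drop = FALSE], 2L, mu0)
  c1 <- sweep(X[y == 1, , drop = FALSE], 2L, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (n0 + n1 - 2)
  list(mu0 = mu0, mu1 = mu1, S = S, tr_p = sum(diag(S)) / ncol(X))
}

.lda_w <- function(suff, lambda) {
  p <- length(suff$mu0)
  Sl <- (1 - lambda) * suff$S
  diag(Sl) <- diag(Sl) + lambda * suff$tr_p
  tryCatch(drop(solve(Sl, suff$mu1 - suff$mu0)), error = function(e) NULL)
}

.auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(rank(scores)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## preprocess one train/test split: age adjustment (group of test subjects is
## never consulted: the training prevalence stands in) then standardization
.preprocess_split <- function(X, y, age, tr, te) {
  Xtr <- X[tr, , drop = FALSE]
  Xte <- X[te, , drop = FALSE]
  if (!is.null(age)) {
    adj <- fit_age_adjustment(Xtr, age[tr], y[tr])
    Xtr <- apply_age_adjustment(adj, Xtr, age[tr], y[tr])
    Xte <- apply_age_adjustment(adj, Xte, age[te],
                                rep(mean(y[tr]), length(te)))
  }
  ctr <- colMeans(Xtr)
  sc <- apply(Xtr, 2L, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  list(tr = sweep(sweep(Xtr, 2L, ctr), 2L, sc, "/"),
       te = sweep(sweep(Xte, 2L, ctr), 2L, sc, "/"))
}

#' Nested cross-validation of the regularized LDA
#'
#' Outer stratified K-fold cross-validation estimates out-of-sample
#' discrimination; within each outer training set, an inner stratified
#' K'-fold loop selects the shrinkage `lambda` by pooled inner out-of-fold
#' AUC. Age adjustment and feature standardization are fitted on the
#' training side of every split (outer and inner) only, so no information
#' about a test subject's label or distribution leaks into its score; test
#' subjects are adjusted using the training-prevalence slope. Weights of the
#' outer-fold models (on the standardized scale) are recorded for stability
#' analysis.
#'
#' @param X feature matrix (subjects x features).
#' @param y 0/1 labels (0 = HS, 1 = OA).
#' @param age optional ages; when supplied the adjustment
#'   ([fit_age_adjustment()]) is part of the in-fold preprocessing.
#' @param config a [cv_config()].
#' @param seed integer seed; the entire procedure is bit-reproducible.
#' @return A `nested_cv_result`: `scores` data.frame (`subject`, `rep`,
#'   `fold`, `label`, `score`, `posterior`), `auc_per_repeat`, `auc_mean`
#'   (headline: mean over repeats of the pooled out-of-fold AUC),
#'   `auc_pooled` (AUC of per-subject mean scores), `weights` (fold x
#'   feature matrix), `lambdas`, `config`, `seed`.
#' @export
nested_cv <- function(X, y, age = NULL, config = cv_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(y) == n, all(y %in% 0:1))
  if (n < 2L * config$outer) stop("too few subjects for the outer folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  lg <- config$lambda_grid
  n_rows <- config$repeats * config$outer
  W <- matrix(NA_real_, n_rows, ncol(X),
              dimnames = list(NULL, colnames(X)))
  lambdas <- numeric(n_rows)
  sc_subject <- integer(0); sc_rep <- integer(0); sc_fold <- integer(0)
  sc_score <- numeric(0); sc_post <- numeric(0)
  auc_rep <- numeric(config$repeats)
  score_sum <- numeric(n)
  row_i <- 0L

  for (r in seq_len(config$repeats)) {
    folds <- .stratified_folds(y, config$outer)
    rep_score <- numeric(n)
    rep_post <- numeric(n)
    for (j in seq_len(config$outer)) {
      te <- which(folds == j); tr <- which(folds != j)
      # inner loop: pooled out-of-fold scores per lambda
      ifolds <- .stratified_folds(y[tr], config$inner)
      inner_scores <- matrix(NA_real_, length(tr), length(lg))
      for (m in seq_len(config$inner)) {
        ite <- which(ifolds == m); itr <- which(ifolds != m)
        sp <- .preprocess_split(X[tr, , drop = FALSE], y[tr], age[tr],
                                itr, ite)
        suff <- .lda_suff(sp$tr, y[tr][itr])
        for (l in seq_along(lg)) {
          w <- .lda_w(suff, lg[l])
          if (is.null(w)) next
          inner_scores[ite, l] <- drop(sp$te %*% w)
        }
      }
      inner_auc <- vapply(seq_along(lg), function(l) {
        s <- inner_scores[, l]
        if (anyNA(s)) return(-Inf)
        .auc_rank(s, y[tr])
      }, numeric(1))
      best <- max(inner_auc)
      lambda <- lg[max(which(inner_auc >= best - 1e-12))]  # ties -> larger
      # final fit on the full outer-training set
      sp <- .preprocess_split(X, y, age, tr, te)
      fit <- fit_rlda(sp$tr, y[tr], lambda)
      pred <- predict(fit, sp$te)
      row_i <- row_i + 1L
      W[row_i, ] <- fit$w
      lambdas[row_i] <- lambda
      rep_score[te] <- pred$score
      rep_post[te] <- pred$posterior
      sc_subject <- c(sc_subject, te)
      sc_rep <- c(sc_rep, rep(r, length(te)))
      sc_fold <- c(sc_fold, rep(j, length(te)))
      sc_score <- c(sc_score, pred$score)
      sc_post <- c(sc_post, pred$posterior)
    }
    auc_rep[r] <- .auc_rank(rep_score, y)
    score_sum <- score_sum + rep_score
  }
  structure(list(
    scores = data.frame(subject = sc_subject, rep = sc_rep, fold = sc_fold,
                        label = y[sc_subject], score = sc_score,
                        posterior = sc_post),
    auc_per_repeat = auc_rep,
    auc_mean = mean(auc_rep),
    auc_pooled = .auc_rank(score_sum / config$repeats, y),
    mean_score = score_sum / config$repeats,
    mean_posterior = vapply(seq_len(n), function(i) {
      mean(sc_post[sc_subject == i])
    }, numeric(1)),
    weights = W, lambdas = lambdas, labels = y,
    config = config, seed = seed),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf(
    "nested CV (%dx%d, %d repeats): mean AUC %.3f (pooled %.3f)\n",
    x$config$outer, x$config$inner, x$config$repeats,
    x$auc_mean, x$auc_pooled))
  invisible(x)
}

#' Permutation test of the nested-CV AUC
#'
#' Tests `H0: AUC = 0.5` against `H1: AUC > 0.5` by permuting the group
#' labels before the entire nested-CV run — age adjustment and shrinkage
#' selection are re-done inside every permutation, so the null distribution
#' reflects the whole procedure. One-sided
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams nested_cv
#' @param n_perm number of label permutations.
#' @return List: `p`, `auc_obs`, `auc_perm` (vector), `n_perm`, `seed`.
#' @export
permutation_test_auc <- function(X, y, age = NULL, config = cv_config(),
                                 n_perm = 999L, seed = 1L) {
  obs <- nested_cv(X, y, age = age, config = config, seed = seed)$auc_mean
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm_seeds <- sample.int(2^31 - 2, n_perm)
  auc_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    nested_cv(X, yp, age = age, config = config, seed = perm_seeds[b])$auc_mean
  }, numeric(1))
  list(p = (1 + sum(auc_perm >= obs)) / (1 + n_perm),
       auc_obs = obs, auc_perm = auc_perm, n_perm = n_perm, seed = seed)
}
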