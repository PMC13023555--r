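## Regularized linear discriminant analysis with a scaled-identity shrinkage
## target, stable when features outnumber effective samples.

#' Fit a regularized LDA
#'
#' Two-class linear discriminant with shrunk pooled covariance
#' `S(lambda) = (1 - lambda) S_pooled + lambda (tr(S)/p) I`. The weight
#' vector is `w = S(lambda)^{-1} (mu1 - mu0)`; posterior probabilities come
#' from the Gaussian class-conditional model with shared covariance and the
#' empirical class prevalence as prior. Features are expected to be
#' standardized on the training data (as [nested_cv()] does).
#'
#' @param X numeric matrix (subjects x features).
#' @param y 0/1 labels; each class needs `>= 2` samples.
#' @param lambda shrinkage intensity in \[0, 1\].
#' @return An `rlda` model: `w`, `b` (intercept), class means, shrunk
#'   covariance, `lambda`, `prior`.
#' @export
fit_rlda <- function(X, y, lambda) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% 0:1), nrow(X) == length(y),
            lambda >= 0, lambda <= 1)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 < 2L || n1 < 2L) stop("each class needs at least 2 samples")
  p <- ncol(X)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  c0 <- sweep(X[y == 0, , drop = FALSE], 2L, mu0)
  c1 <- sweep(X[y == 1, , drop = FALSE], 2L, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (n0 + n1 - 2)
  Sl <- (1 - lambda) * S + lambda * (sum(diag(S)) / p) * diag(p)
  if (rcond(Sl) < 1e-12) {
    stop("singular pooled covariance: increase the shrinkage (lambda > 0)")
  }
  w <- drop(solve(Sl, mu1 - mu0))
  prior <- n1 / (n0 + n1)
  b <- drop(-0.5 * crossprod(mu0 + mu1, w)) + log(prior / (1 - prior))
  structure(list(w = stats::setNames(w, colnames(X)), b = b,
                 mu0 = mu0, mu1 = mu1, cov = Sl,
                 lambda = lambda, prior = prior),
            class = "rlda")
}

#' Discriminant scores and posteriors from a fitted rLDA
#'
#' @param object an `rlda` model.
#' @param X feature matrix.
#' @param ... unused.
#' @return List with `score` (`X w`) and `posterior`
#'   (`P(group = 1 | x)` via the logistic of `X w + b`).
#' @export
predict.rlda <- function(object, X, ...) {
  s <- drop(as.matrix(X) %*% object$w)
  list(score = s, posterior = stats::plogis(s + object$b))
}
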