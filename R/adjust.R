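## Age adjustment of features: Y ~ Age + Group + Age x Group, fitted on
## training subjects only and applied out-of-fold.

#' Fit the per-feature age-adjustment regression
#'
#' For every feature, fits ordinary least squares
#' `Y ~ 1 + (age - mean(age)) * group` on the (training) subjects. The
#' age-centered design keeps the group intercepts interpretable at the
#' training mean age.
#'
#' @param X numeric matrix or data.frame of features (subjects x features).
#' @param age numeric vector of ages (years).
#' @param group 0/1 group indicator (0 = HS, 1 = OA); both groups must be
#'   present and `n >= 4`.
#' @return An `age_adjustment` model: coefficient matrix (4 x features:
#'   intercept, beta_age, beta_group, beta_interaction) and the training age
#'   mean.
#' @export
fit_age_adjustment <- function(X, age, group) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(age) == n, length(group) == n)
  if (n < 4L) stop("need at least 4 subjects to fit the adjustment")
  if (length(unique(group)) < 2L) stop("both groups must be present")
  agec <- age - mean(age)
  D <- cbind(intercept = 1, age = agec, group = group, age_group = agec * group)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient adjustment design")
  coef <- qr.coef(qrD, X)
  rownames(coef) <- colnames(D)
  if (!all(is.finite(coef))) stop("non-finite adjustment coefficients")
  structure(list(coef = coef, age_mean = mean(age),
                 features = colnames(X)),
            class = "age_adjustment")
}

#' Apply an age adjustment out-of-fold
#'
#' Subtracts the group-specific age slope about the training age mean:
#' `Y_adj = Y - (beta_age + beta_interaction * group) * (age - age_mean)`.
#' Group intercept differences — the disease signal — are preserved; only
#' the age trend is removed. `group` may be fractional (e.g. the training
#' prevalence) when the group of a subject must not be consulted, as for
#' test folds inside cross-validation.
#'
#' @param model an `age_adjustment` from [fit_age_adjustment()].
#' @param X features to adjust (same columns as at fit time).
#' @param age,group covariates of these subjects.
#' @return Adjusted matrix of the same shape.
#' @export
apply_age_adjustment <- function(model, X, age, group) {
  stopifnot(inherits(model, "age_adjustment"))
  X <- as.matrix(X)
  agec <- age - model$age_mean
  slope_age <- model$coef["age", , drop = FALSE]
  slope_int <- model$coef["age_group", , drop = FALSE]
  X - agec %*% slope_age - (agec * group) %*% slope_int
}
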