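## ROC/AUC and the evaluation suite: bootstrap CI, DeLong comparison,
## calibration/Brier, decision curves.

#' ROC curve and AUC
#'
#' Trapezoidal AUC with ties counted as 1/2 — numerically identical to the
#' normalized Mann-Whitney U statistic. The curve is returned as one
#' (FPR, TPR) point per distinct threshold.
#'
#' @param scores numeric discriminant scores (higher = more OA-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return List: `auc`, `curve` (`data.frame` with `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc <- (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    fpr = c(0, vapply(th, function(u) sum(scores >= u & labels == 0) / n0,
                      numeric(1))),
    tpr = c(0, vapply(th, function(u) sum(scores >= u & labels == 1) / n1,
                      numeric(1))))
  list(auc = auc, curve = curve)
}

#' Bootstrap confidence interval for the AUC
#'
#' Subject-level resampling with replacement; percentile interval. Resamples
#' that lose one of the classes are redrawn.
#'
#' @param scores,labels as in [roc_auc()].
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return List: `auc`, `ci` (length-2), `B`, `boot` (resampled AUCs).
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000L, seed = 1L,
                             conf = 0.95) {
  labels <- as.integer(labels)
  n <- length(scores)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    boot[b] <- roc_auc(scores[idx], labels[idx])$auc
  }
  alpha <- (1 - conf) / 2
  list(auc = roc_auc(scores, labels)$auc,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       B = B, boot = boot)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets on the same subjects using the
#' placement-value (structural components) covariance estimator; two-sided
#' p-value from the normal reference. Antisymmetric in the two models.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared 0/1 labels.
#' @return List: `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); k <- length(neg)
  if (m < 2L || k < 2L) stop("need >= 2 subjects per class")
  placements <- function(s) {
    psi <- outer(s[pos], s[neg],
                 function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  Smat <- s10 / m + s01 / k
  d <- pa$auc - pb$auc
  v <- Smat[1, 1] + Smat[2, 2] - 2 * Smat[1, 2]
  if (v <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = 0,
                z = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(v), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Calibration curve and Brier score
#'
#' Bins predicted probabilities into equal-width bins and contrasts the mean
#' prediction with the observed event fraction per bin; the Brier score is
#' the mean squared error `mean((posterior - label)^2)`.
#'
#' @param posteriors predicted probabilities in \[0, 1\].
#' @param labels 0/1 outcomes.
#' @param n_bins number of equal-width bins.
#' @return List: `brier`, `curve` (`data.frame`: `bin_mid`, `mean_pred`,
#'   `obs_frac`, `n`).
#' @export
calibration_brier <- function(posteriors, labels, n_bins = 10L) {
  labels <- as.integer(labels)
  stopifnot(length(posteriors) == length(labels),
            all(posteriors >= 0 & posteriors <= 1))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(posteriors, breaks, include.lowest = TRUE, labels = FALSE)
  curve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    data.frame(bin_mid = (breaks[b] + breaks[b + 1L]) / 2,
               mean_pred = if (any(sel)) mean(posteriors[sel]) else NA_real_,
               obs_frac = if (any(sel)) mean(labels[sel]) else NA_real_,
               n = sum(sel))
  }))
  list(brier = mean((posteriors - labels)^2), curve = curve)
}

#' Decision-curve analysis
#'
#' Net benefit of treating subjects whose predicted probability exceeds a
#' threshold `pt`: `NB(pt) = TP/N - (FP/N) pt/(1 - pt)`, compared with the
#' treat-all strategy (`prevalence - (1 - prevalence) pt/(1 - pt)`) and
#' treat-none (identically 0).
#'
#' @param posteriors predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param thresholds threshold probability grid.
#' @return `data.frame`: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(posteriors, labels,
                           thresholds = seq(0.05, 0.95, by = 0.01)) {
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  out <- do.call(rbind, lapply(thresholds, function(pt) {
    treat <- posteriors >= pt
    tp <- sum(treat & labels == 1) / n
    fp <- sum(treat & labels == 0) / n
    odds <- pt / (1 - pt)
    data.frame(threshold = pt,
               nb_model = tp - fp * odds,
               nb_all = prev - (1 - prev) * odds,
               nb_none = 0)
  }))
  rownames(out) <- NULL
  out
}
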