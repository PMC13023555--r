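## Nonparametric univariate battery: Mann-Whitney U, Cliff's delta,
## Benjamini-Hochberg FDR, and a permutation MANOVA on discriminant scores.

#' Mann-Whitney U test with Cliff's delta
#'
#' Two-sided test for a location difference between two samples, with the
#' effect size derived from the same U statistic: `delta = 2U/(n1 n2) - 1`,
#' where U counts pairs with `x > y` (ties as 1/2, via midranks). The
#' p-value uses exact enumeration for small tie-free samples (both `n <= 20`)
#' and the tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric samples (each of size `>= 2`).
#' @return `data.frame` row: `U`, `p`, `delta`, `n1`, `n2`.
#' @export
mann_whitney_cliffs <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 observations")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 <= 20L && n2 <= 20L && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  data.frame(U = U, p = p, delta = 2 * U / (n1 * n2) - 1, n1 = n1, n2 = n2)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control with monotonicity enforcement; order-preserving.
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same order as the input).
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Univariate feature battery
#'
#' Runs [mann_whitney_cliffs()] on every feature of a feature table, adjusts
#' p-values across features by [bh_fdr()], and appends group medians/IQRs.
#'
#' @param ft a feature table from [build_feature_table()].
#' @param group optional 0/1 vector (defaults to `ft$group`).
#' @return `data.frame`, one row per feature: `U`, `p`, `p_adj`, `delta`,
#'   and the group summaries.
#' @export
univariate_battery <- function(ft, group = ft$group) {
  feats <- feature_columns(ft)
  rows <- do.call(rbind, lapply(feats, function(f) {
    # OA (group 1) as the first sample: delta > 0 means OA values run higher
    mann_whitney_cliffs(ft[[f]][group == 1], ft[[f]][group == 0])
  }))
  rows$feature <- feats
  rows$p_adj <- bh_fdr(rows$p)
  merge(rows[c("feature", "U", "p", "p_adj", "delta")],
        summarize_features(ft, group), by = "feature", sort = FALSE)
}

#' Permutation MANOVA on discriminant scores
#'
#' Tests group separation of (possibly multivariate) scores with an
#' eigenvalue-based statistic: the Lawley-Hotelling trace
#' `sum(eigen(W^-1 B))` of the between- over within-group scatter, whose
#' null distribution is obtained by label permutation. The statistic is
#' invariant to affine rescaling of the scores. The p-value is
#' `(1 + #\{perm >= obs\}) / (1 + n_perm)`.
#'
#' @param scores numeric vector or matrix (rows = subjects).
#' @param labels group labels (two or more groups).
#' @param n_perm number of permutations, `>= 99`.
#' @param seed RNG seed.
#' @return List: `statistic`, `p`, `n_perm`.
#' @export
np_manova <- function(scores, labels, n_perm = 999L, seed = 1L) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  stopifnot(nrow(scores) == length(labels), n_perm >= 99L)
  if (all(apply(scores, 2L, function(c) stats::var(c) == 0))) {
    stop("constant scores: separation statistic undefined")
  }
  trace_stat <- function(lab) {
    mu <- colMeans(scores)
    W <- matrix(0, ncol(scores), ncol(scores))
    B <- W
    for (g in levels(lab)) {
      sel <- lab == g
      mg <- colMeans(scores[sel, , drop = FALSE])
      cg <- sweep(scores[sel, , drop = FALSE], 2L, mg)
      W <- W + crossprod(cg)
      B <- B + sum(sel) * tcrossprod(mg - mu)
    }
    sum(diag(solve(W, B)))
  }
  obs <- trace_stat(labels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) trace_stat(sample(labels)), numeric(1))
  list(statistic = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}
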