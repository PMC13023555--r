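## Fold-weight stability: which features drive the discriminant, and how
## reproducibly across cross-validation folds.

#' Stability of LDA weights across cross-validation folds
#'
#' Summarizes the per-feature distribution of standardized LDA weights
#' recorded over outer folds and repeats: a high `|mean|` marks an important
#' feature, a low variance a stable estimate; the stability statistic is
#' `|mean| / sd`. Optionally, per-feature significance is assessed against a
#' label-permutation null of the same nested-CV procedure: labels are
#' permuted, the whole nested CV rerun, and each feature's observed
#' statistic compared with its own permutation distribution,
#' `p = (1 + #\{null >= obs\}) / (1 + n_perm)`, followed by BH adjustment.
#'
#' @param weights fold x feature weight matrix (e.g. the `weights` element
#'   of a [nested_cv()] result).
#' @param X,y,age,config the inputs of the original [nested_cv()] run; only
#'   needed when `n_perm > 0`.
#' @param n_perm number of label permutations for the significance
#'   assessment (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return `data.frame`, one row per feature, ordered by decreasing
#'   stability: `feature`, `mean`, `variance`, `stability`
#'   (`|mean|/sd`; `Inf` for constant nonzero weights), `rank`, and, when
#'   permuted, `p` and `p_adj`.
#' @export
weight_stability <- function(weights, X = NULL, y = NULL, age = NULL,
                             config = NULL, n_perm = 0L, seed = 1L) {
  weights <- as.matrix(weights)
  stat_of <- function(W) {
    mu <- colMeans(W)
    sdv <- apply(W, 2L, stats::sd)
    ifelse(sdv == 0, ifelse(mu == 0, 0, Inf), abs(mu) / sdv)
  }
  mu <- colMeans(weights)
  va <- apply(weights, 2L, stats::var)
  st <- stat_of(weights)
  out <- data.frame(feature = colnames(weights) %||%
                      paste0("f", seq_along(mu)),
                    mean = mu, variance = va, stability = st)
  if (n_perm > 0L) {
    stopifnot(!is.null(X), !is.null(y), !is.null(config))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    perm_seeds <- sample.int(2^31 - 2, n_perm)
    null_stats <- matrix(NA_real_, n_perm, ncol(weights))
    for (b in seq_len(n_perm)) {
      yp <- sample(as.integer(y))
      res <- nested_cv(X, yp, age = age, config = config,
                       seed = perm_seeds[b])
      null_stats[b, ] <- stat_of(res$weights)
    }
    out$p <- vapply(seq_len(ncol(weights)), function(j) {
      (1 + sum(null_stats[, j] >= st[j])) / (1 + n_perm)
    }, numeric(1))
    out$p_adj <- bh_fdr(out$p)
  }
  out <- out[order(-out$stability), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
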