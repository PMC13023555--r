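#!/usr/bin/env Rscript
# Multivariate analysis: regularized LDA under nested cross-validation for
# each model (ME/SE/BE) and scope (global/multi-ROI), with bootstrap CIs,
# permutation tests (BH-corrected across models), DeLong comparisons,
# calibration, decision curves and weight stability. Run after
# 03_fit_models.R. Writes results/classification.json and curve CSVs.

suppressPackageStartupMessages(library(t2oa))

seed <- 7L
cv <- cv_config(outer = 5, inner = 5, repeats = 20)
n_perm <- 199L
n_boot <- 2000L

runs <- expand.grid(model = c("me", "se", "be"),
                    scope = c("global", "multi"),
                    stringsAsFactors = FALSE)
results <- list()
mean_scores <- list()
labels_ref <- NULL

for (k in seq_len(nrow(runs))) {
  model <- runs$model[k]; scope <- runs$scope[k]
  ft <- read.csv(sprintf("results/features_%s_%s.csv", model, scope))
  feats <- setdiff(names(ft), c("subject", "group", "age", "sex", "bmi"))
  X <- as.matrix(ft[, feats, drop = FALSE])
  labels_ref <- ft$group
  res <- nested_cv(X, ft$group, age = ft$age, config = cv, seed = seed)
  ci <- bootstrap_auc_ci(res$mean_score, ft$group, B = n_boot, seed = seed)
  pt <- permutation_test_auc(X, ft$group, age = ft$age,
                             config = cv_config(cv$outer, cv$inner,
                                                repeats = 2),
                             n_perm = n_perm, seed = seed)
  cal <- calibration_brier(res$mean_posterior, ft$group)
  dc <- decision_curve(res$mean_posterior, ft$group)
  ws <- weight_stability(res$weights)
  mano <- np_manova(res$mean_score, ft$group, n_perm = 999, seed = seed)

  tag <- paste(model, scope, sep = "_")
  mean_scores[[tag]] <- res$mean_score
  results[[tag]] <- list(
    model = model, scope = scope, n_features = length(feats),
    auc_mean = res$auc_mean, auc_pooled = res$auc_pooled,
    auc_ci95 = ci$ci, perm_p = pt$p, manova_p = mano$p,
    brier = cal$brier, seed = seed,
    lambda_median = median(res$lambdas),
    top_features = ws$feature[1:3])
  write.csv(dc, sprintf("results/decision_curve_%s.csv", tag),
            row.names = FALSE)
  write.csv(cal$curve, sprintf("results/calibration_%s.csv", tag),
            row.names = FALSE)
  write.csv(roc_auc(res$mean_score, ft$group)$curve,
            sprintf("results/roc_%s.csv", tag), row.names = FALSE)
  cat(sprintf(
    "%-9s AUC %.2f [%.2f, %.2f], perm p = %.3f, Brier %.2f, top: %s\n",
    tag, res$auc_mean, ci$ci[1], ci$ci[2], pt$p, cal$brier,
    paste(ws$feature[1:3], collapse = ", ")))
}

# BH across the six model-level permutation p-values
perm_p <- vapply(results, `[[`, numeric(1), "perm_p")
p_adj <- bh_fdr(perm_p)
for (k in seq_along(results)) results[[k]]$perm_p_adj <- p_adj[k]

# pairwise DeLong between models within each scope
for (scope in c("global", "multi")) {
  for (pair in list(c("be", "me"), c("be", "se"), c("se", "me"))) {
    a <- paste(pair[1], scope, sep = "_"); b <- paste(pair[2], scope, sep = "_")
    dl <- delong_test(mean_scores[[a]], mean_scores[[b]], labels_ref)
    results[[paste("delong", a, "vs", b, sep = "_")]] <-
      list(diff = dl$diff, p = dl$p)
    cat(sprintf("DeLong %s vs %s: dAUC %+0.3f, p = %.2f\n",
                a, b, dl$diff, dl$p))
  }
}

jsonlite::write_json(results, "results/classification.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/classification.json\n")
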