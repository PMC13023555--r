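#!/usr/bin/env Rscript
# Calibration of the whole decision machinery on exact-null cohorts: the
# nested-CV AUC should average 0.5 and the permutation test should reject at
# its nominal 5% rate. Writes results/null_calibration.csv.

suppressPackageStartupMessages(library(t2oa))
dir.create("results", showWarnings = FALSE)

n_rep <- 200L
cv <- cv_config(outer = 3, inner = 3, repeats = 1,
                lambda_grid = c(0.01, 0.1, 0.5, 1))
n_perm <- 39L

aucs <- numeric(n_rep); pvals <- numeric(n_rep)
for (i in seq_len(n_rep)) {
  cohort <- generate_null_cohort(cohort_config(), seed = 80000 + i)
  ft <- cohort_true_features(cohort)
  X <- as.matrix(ft[, feature_columns(ft)])
  pt <- permutation_test_auc(X, ft$group, age = ft$age, config = cv,
                             n_perm = n_perm, seed = i)
  aucs[i] <- pt$auc_obs; pvals[i] <- pt$p
}

write.csv(data.frame(rep = seq_len(n_rep), auc = aucs, perm_p = pvals),
          "results/null_calibration.csv", row.names = FALSE)
cat(sprintf("null nested-CV AUC: mean %.3f (sd %.3f) over %d cohorts\n",
            mean(aucs), sd(aucs), n_rep))
cat(sprintf("permutation rejection rate at alpha = 0.05: %.3f\n",
            mean(pvals <= 0.05)))
cat("both should sit at their nominal values (0.5 and 0.05) within\n")
cat("Monte-Carlo error; systematic departures would indicate leakage in\n")
cat("the fold-wise preprocessing or an invalid permutation scheme.\n")
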