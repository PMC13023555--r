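make_label_block <- function() {
  # six 2x1x1 blocks along x
  labels <- array(0L, c(12, 1, 1))
  for (k in 1:6) labels[(k - 1) * 2 + 1:2, 1, 1] <- k
  labels
}

test_that("constant maps yield identical ROI and global means", {
  labels <- make_label_block()
  maps <- list(t2 = array(42.4, dim(labels)))
  rm <- extract_roi_means(maps, labels)
  expect_equal(rm$t2, rep(42.4, 7))
  expect_equal(rm$roi, c("PC", "TrC", "MFC", "MTC", "LFC", "LTC", "Global"))
})

test_that("the global mean is voxel-weighted, not a mean of ROI means", {
  labels <- array(0L, c(4, 1, 1))
  labels[1:3, 1, 1] <- 1L  # PC: 3 voxels at 10
  labels[4, 1, 1] <- 2L    # TrC: 1 voxel at 50
  maps <- list(t2 = array(c(10, 10, 10, 50), c(4, 1, 1)))
  rm <- suppressWarnings(extract_roi_means(maps, labels))
  expect_equal(rm$t2[rm$roi == "Global"], 20)  # (3*10 + 50) / 4, not 30
  # and equals the voxel-count-weighted combination of ROI means exactly
  sub <- rm[rm$roi %in% c("PC", "TrC"), ]
  expect_equal(rm$t2[rm$roi == "Global"],
               sum(sub$t2 * sub$n_voxels) / sum(sub$n_voxels),
               tolerance = 1e-12)
})

test_that("non-converged voxels are excluded exactly", {
  labels <- make_label_block()
  vals <- array(seq_len(12) + 0.5, dim(labels))
  pm <- structure(list(model = "me", values = list(t2 = vals),
                       converged = array(TRUE, dim(labels)),
                       dim = dim(labels)),
                  class = "parameter_map")
  pm$converged[1, 1, 1] <- FALSE
  rm <- extract_roi_means(pm, labels)
  expect_equal(rm$t2[rm$roi == "PC"], vals[2, 1, 1])
  expect_equal(rm$t2[rm$roi == "Global"], mean(vals[2:12]))
  expect_equal(rm$n_voxels[rm$roi == "Global"], 11L)
})

test_that("ROI means are invariant to voxel order and flag empty labels", {
  labels <- make_label_block()
  set.seed(41)
  vals <- array(rnorm(12), dim(labels))
  rm1 <- extract_roi_means(list(t2 = vals), labels)
  perm <- sample(1:2)  # permute within the first block
  vals2 <- vals; vals2[1:2, 1, 1] <- vals[perm, 1, 1]
  rm2 <- extract_roi_means(list(t2 = vals2), labels)
  expect_equal(rm1$t2, rm2$t2)
  labels3 <- labels; labels3[labels3 == 6L] <- 0L
  expect_warning(extract_roi_means(list(t2 = vals), labels3), "LTC")
  expect_error(extract_roi_means(list(t2 = vals), array(1L, c(3, 1, 1))),
               "grid")
})

fake_roi_means <- function(subjects, params) {
  rois <- c(names(roi_legend()), "Global")
  out <- expand.grid(subject = subjects, roi = rois,
                     stringsAsFactors = FALSE)
  for (p in params) out[[p]] <- runif(nrow(out), 1, 2)
  out
}

covs <- data.frame(subject = 1:6, group = rep(0:1, 3),
                   age = c(50, 61, 55, 66, 48, 70))

test_that("feature tables have the documented sizes and column order", {
  set.seed(42)
  cases <- list(me = c(6L, 1L), se = c(12L, 2L), be = c(18L, 3L))
  for (m in names(cases)) {
    rm <- fake_roi_means(1:6, model_param_names(m))
    multi <- build_feature_table(rm, covs, m, "multi")
    global <- build_feature_table(rm, covs, m, "global")
    expect_length(feature_columns(multi), cases[[m]][1])
    expect_length(feature_columns(global), cases[[m]][2])
  }
  # parameter-major order with the canonical ROI sequence
  rm <- fake_roi_means(1:6, model_param_names("be"))
  ft <- build_feature_table(rm, covs, "be", "multi")
  expect_identical(feature_columns(ft)[1:6],
                   paste0("f_", c("PC", "TrC", "MFC", "MTC", "LFC", "LTC")))
  expect_identical(feature_columns(ft)[7], "t2_short_PC")
})

test_that("subjects with missing core features are dropped with a message", {
  set.seed(43)
  rm <- fake_roi_means(1:6, "t2")
  rm <- rm[!(rm$subject == 3 & rm$roi == "MFC"), ]
  expect_message(ft <- build_feature_table(rm, covs, "me", "multi"),
                 "dropping 1")
  expect_equal(nrow(ft), 5L)
  expect_false(3 %in% ft$subject)
})
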