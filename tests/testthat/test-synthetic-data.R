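test_that("cohort generation matches the configured group sizes and ranges", {
  ch <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(ch$covariates), 52L)
  expect_equal(sum(ch$covariates$group == 0), 26L)
  expect_equal(sum(ch$covariates$group == 1), 26L)
  expect_true(all(ch$covariates$age >= 40 & ch$covariates$age <= 75))
  box <- model_box("be")
  tr <- ch$roi_truth[ch$roi_truth$roi != "Global", ]
  for (p in c("f", "t2_short", "t2_long")) {
    expect_true(all(tr[[p]] >= box$lower[[p]] & tr[[p]] <= box$upper[[p]]))
  }
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_hs = 4, n_oa = 4, grid = c(2, 2, 1))
  a <- generate_cohort(cfg, seed = 7, output = "images")
  b <- generate_cohort(cfg, seed = 7, output = "images")
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$roi_truth, b$roi_truth)
  expect_identical(a$images[[3]]$series$voxels, b$images[[3]]$series$voxels)
  c2 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$roi_truth, c2$roi_truth))
})

test_that("noise-free, dispersion-free cohorts pass group medians through the pipeline", {
  cfg <- cohort_config(n_hs = 1, n_oa = 1, sd_scale = 0, snr = Inf,
                       grid = c(2, 1, 1))
  ch <- generate_cohort(cfg, seed = 3, output = "images")
  ref <- cfg$reference
  for (i in 1:2) {
    g <- c("hs", "oa")[ch$covariates$group[i] + 1]
    pm <- fit_map(ch$images[[i]]$series, ch$images[[i]]$labels > 0, "be")
    rm <- extract_roi_means(pm, ch$images[[i]]$labels)
    for (r in names(roi_legend())) for (p in c("f", "t2_short", "t2_long")) {
      want <- ref$median[ref$group == g & ref$roi == r & ref$param == p]
      expect_equal(rm[[p]][rm$roi == r], want, tolerance = 1e-4)
    }
  }
})

test_that("null cohorts draw both groups from one distribution", {
  cfg <- cohort_config(n_hs = 40, n_oa = 40)
  ch <- generate_null_cohort(cfg, seed = 9)
  expect_equal(sum(ch$covariates$group == 1), 40L)
  tr <- merge(ch$roi_truth[ch$roi_truth$roi == "MTC", ], ch$covariates,
              by = "subject")
  # group means of a latent parameter agree within sampling noise
  d <- abs(mean(tr$t2_long[tr$group == 1]) - mean(tr$t2_long[tr$group == 0]))
  expect_lt(d, 3 * sd(tr$t2_long) / sqrt(20))
  expect_null(ch$config$group_shift_sd)
})

test_that("configured group shifts move only the targeted ROI parameters", {
  cfg <- cohort_config(n_hs = 150, n_oa = 150, identical_groups = TRUE,
                       group_shift_sd = list(MFC = c(t2_long = 1.5)))
  ch <- generate_cohort(cfg, seed = 10)
  tr <- merge(ch$roi_truth, ch$covariates, by = "subject")
  sd_ref <- cfg$reference$sd[cfg$reference$group == "hs" &
                             cfg$reference$roi == "MFC" &
                             cfg$reference$param == "t2_long"]
  shift_mfc <- mean(tr$t2_long[tr$roi == "MFC" & tr$group == 1]) -
    mean(tr$t2_long[tr$roi == "MFC" & tr$group == 0])
  shift_lfc <- mean(tr$t2_long[tr$roi == "LFC" & tr$group == 1]) -
    mean(tr$t2_long[tr$roi == "LFC" & tr$group == 0])
  expect_lt(abs(shift_mfc - 1.5 * sd_ref), 0.35 * sd_ref)
  expect_lt(abs(shift_lfc), 0.35 * sd_ref)
})

test_that("image output renders the six-block label geometry", {
  cfg <- cohort_config(n_hs = 1, n_oa = 1, grid = c(3, 2, 1))
  ch <- generate_cohort(cfg, seed = 11, output = "images")
  labels <- ch$images[[1]]$labels
  expect_equal(dim(labels), c(18, 2, 1))
  expect_equal(sort(unique(as.vector(labels))), 1:6)
  expect_equal(sum(labels == 4), 6)
  series <- ch$images[[1]]$series
  expect_equal(dim(series$voxels), c(18, 2, 1, 7))
})
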