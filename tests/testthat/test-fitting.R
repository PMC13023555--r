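sched7 <- default_pte_schedule()

test_that("noiseless ME recovery matches the closed-form two-point solution", {
  sig <- me_signal(me_params(50, 40), sched7)
  fit <- fit_voxel(sig, sched7, "me")
  # log-linear oracle from the 0 and 55 ms echoes
  t2_closed <- 55 / log(Mod(sig[1]) / Mod(sig[6]))
  expect_lt(abs(fit$theta[["t2"]] - t2_closed) / t2_closed, 1e-6)
  expect_lt(abs(fit$theta[["t2"]] - 40) / 40, 1e-6)
  expect_equal(Mod(fit$A), 50, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("SE fit of alpha = 1 data recovers the nesting identity", {
  sig <- se_signal(se_params(30, 60, 1), sched7)
  fit <- fit_voxel(sig, sched7, "se")
  expect_lt(abs(fit$theta[["alpha"]] - 1), 1e-4)
  expect_lt(abs(fit$theta[["t2"]] - 60) / 60, 1e-3)
})

test_that("noiseless BE recovery agrees with a grid-search oracle", {
  truth <- c(f = 0.25, t2_short = 5, t2_long = 50)
  sig <- be_signal(be_params(40, 0.25, 5, 50), sched7)
  fit <- fit_voxel(sig, sched7, "be")
  for (p in names(truth)) {
    expect_lt(abs(fit$theta[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  }
  # independent coarse 3D grid search over the box: the SSR minimum must sit
  # at the grid point nearest the truth
  fgrid <- seq(0.05, 0.95, by = 0.05)
  tsgrid <- seq(0.5, 10, by = 0.5)
  tlgrid <- seq(20, 300, by = 10)
  t <- sched7$ptes
  best <- NULL; best_ssr <- Inf
  for (f in fgrid) for (ts in tsgrid) for (tl in tlgrid) {
    g <- f * exp(-t / ts) + (1 - f) * exp(-t / tl)
    a <- sum(g * Re(sig)) / sum(g * g)   # profiled amplitude
    ssr <- sum((a * g - Re(sig))^2)
    if (ssr < best_ssr) { best_ssr <- ssr; best <- c(f, ts, tl) }
  }
  expect_equal(best, c(0.25, 5, 50))
})

test_that("the returned fit dominates every initialization point", {
  set.seed(31)
  sig <- add_complex_noise(be_signal(be_params(100, 0.3, 6, 60), sched7), 2)
  fit <- fit_voxel(sig, sched7, "be")
  expect_true(all(fit$residual_norm <= fit$start_residuals + 1e-10))
  expect_identical(fit$n_starts_used, nrow(default_starts("be")))
})

test_that("the BE fit matches or beats the ME fit up to its boundary gap", {
  # BE nests ME only at the f = 0.01 box edge, where a residual short-pool
  # contamination of at most 0.01 * A per echo remains; the BE optimum can
  # therefore sit above the ME optimum by at most that contamination.
  set.seed(32)
  gap <- (0.01 * 80)^2 * length(sched7$ptes) * 2
  for (i in 1:5) {
    sig <- add_complex_noise(me_signal(me_params(80, runif(1, 25, 60)),
                                       sched7), 1.5)
    r_me <- fit_voxel(sig, sched7, "me")$residual_norm
    r_be <- fit_voxel(sig, sched7, "be")$residual_norm
    expect_lte(r_be^2, r_me^2 + gap)
  }
})

test_that("degenerate and malformed voxels are flagged, not fatal", {
  z <- fit_voxel(rep(0 + 0i, 7), sched7, "me")
  expect_false(z$converged)
  expect_true(is.na(z$theta[["t2"]]))
  expect_error(fit_voxel(rep(1 + 0i, 5), sched7, "me"), "length")
})

test_that("map fitting is voxel-independent and honors the mask", {
  sig <- me_signal(me_params(50, 40), sched7)
  vox <- array(0i, c(2, 2, 1, 7))
  for (i in 1:2) for (j in 1:2) vox[i, j, 1, ] <- sig
  series <- image_series(vox, sched7)
  mask <- array(TRUE, c(2, 2, 1))
  pm <- fit_map(series, mask, "me")
  t2s <- pm$values$t2[mask]
  expect_equal(t2s, rep(t2s[1], 4))
  expect_equal(t2s[1], 40, tolerance = 1e-5)
  # excluded voxel stays missing
  mask2 <- mask; mask2[2, 2, 1] <- FALSE
  pm2 <- fit_map(series, mask2, "me")
  expect_true(is.na(pm2$values$t2[2, 2, 1]))
  expect_false(anyNA(pm2$values$t2[mask2]))
  expect_error(fit_map(series, array(FALSE, c(2, 2, 1)), "me"), "empty mask")
})

test_that("a two-block phantom recovers its two T2 values within noise", {
  set.seed(33)
  t2_true <- c(30, 60)
  vox <- array(0i, c(4, 2, 1, 7))
  for (i in 1:4) for (j in 1:2) {
    t2 <- t2_true[(i > 2) + 1]
    vox[i, j, 1, ] <- add_complex_noise(me_signal(me_params(100, t2), sched7), 2)
  }
  pm <- fit_map(image_series(vox, sched7), array(TRUE, c(4, 2, 1)), "me")
  m1 <- mean(pm$values$t2[1:2, , 1])
  m2 <- mean(pm$values$t2[3:4, , 1])
  expect_lt(abs(m1 - 30) / 30, 0.1)
  expect_lt(abs(m2 - 60) / 60, 0.1)
})
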