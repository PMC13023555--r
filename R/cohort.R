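## Synthetic two-group cohort generator. Ground truth is bi-exponential:
## per-subject, per-ROI BE parameters are drawn around group-level medians
## (defaults: the reference distributions below), voxel signals are BE decays
## with complex Gaussian noise, and ME/SE fits to these data are then
## intentionally misspecified — as they are on real cartilage.

#' Reference sub-regional BE parameter distributions
#'
#' Group-level medians and interquartile ranges of the bi-exponential
#' parameters (`f`, `t2_short`, `t2_long`) per cartilage sub-region, for a
#' healthy (HS) and an early-OA group, as observed in 3T knee studies of
#' this design. IQRs are converted to Gaussian scales via
#' `sd = IQR / 1.349` (a normality approximation, used only to seed the
#' generator).
#'
#' @return `data.frame`: `group` (`"hs"`/`"oa"`), `roi`, `param`, `median`,
#'   `iqr_lo`, `iqr_hi`, `sd`.
#' @export
be_reference <- function() {
  rois <- names(roi_legend())
  val <- function(param, group, med, lo, hi) {
    data.frame(group = group, roi = rois, param = param,
               median = med, iqr_lo = lo, iqr_hi = hi,
               sd = (hi - lo) / 1.349)
  }
  rbind(
    val("f", "hs", c(0.14, 0.17, 0.24, 0.27, 0.24, 0.26),
        c(0.09, 0.14, 0.18, 0.22, 0.21, 0.21),
        c(0.20, 0.20, 0.30, 0.30, 0.40, 0.30)),
    val("f", "oa", c(0.16, 0.19, 0.26, 0.25, 0.26, 0.20),
        c(0.13, 0.17, 0.20, 0.19, 0.18, 0.16),
        c(0.21, 0.24, 0.31, 0.31, 0.30, 0.30)),
    val("t2_short", "hs", c(6.0, 5.9, 5.7, 5.6, 5.4, 5.7),
        c(5.5, 5.2, 5.1, 5.0, 4.7, 5.0),
        c(6.3, 6.1, 6.0, 6.0, 6.0, 6.1)),
    val("t2_short", "oa", c(5.8, 5.6, 5.2, 5.4, 5.2, 5.4),
        c(5.6, 5.3, 4.6, 4.8, 4.8, 5.0),
        c(6.2, 6.1, 5.7, 5.6, 5.5, 5.8)),
    val("t2_long", "hs", c(58.1, 58.5, 55.3, 49.4, 65.4, 47.3),
        c(48.9, 47.1, 43.9, 42.1, 51.6, 42.2),
        c(80.0, 84.4, 85.5, 53.3, 91.8, 54.5)),
    val("t2_long", "oa", c(55.0, 56.0, 57.0, 55.2, 47.2, 39.8),
        c(46.6, 47.0, 44.5, 47.2, 38.2, 30.9),
        c(66.6, 73.5, 76.4, 74.0, 61.1, 47.3)))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a 26 HS / 26 early-OA study: group ages 51.5 +/- 8.4 and
#' 61.8 +/- 7.6 years truncated to 40-75, female fractions 10/26 and 19/26,
#' BMI 27.3/27.8, sub-regional BE parameters from [be_reference()], the
#' 7-point pTE schedule, amplitude 100 with per-channel noise
#' `amplitude / snr` (SNR 50 at t = 0), and an 8 x 8 x 2 voxel block per
#' sub-region.
#'
#' @param n_hs,n_oa subjects per group.
#' @param age_mean,age_sd,age_range group age distributions (years),
#'   truncated to `age_range`.
#' @param female_prob per-group probability of female sex.
#' @param bmi_mean,bmi_sd per-group BMI distribution.
#' @param reference per-ROI parameter distribution table ([be_reference()]).
#' @param sd_scale multiplier on all between-subject SDs.
#' @param age_slope named per-parameter slope (units/year) of the latent
#'   parameters on age, shared by both groups; default none.
#' @param identical_groups draw both groups from the HS distributions
#'   (exact-null backbone; combine with `group_shift_sd` for controlled
#'   effects).
#' @param group_shift_sd optional named list `ROI -> named vector` adding
#'   `shift * sd` to the OA group's parameter medians, e.g.
#'   `list(MFC = c(t2_long = 1.5))`.
#' @param amplitude complex signal amplitude at t = 0.
#' @param snr per-channel SNR at t = 0; voxel noise sd is
#'   `amplitude / snr`.
#' @param schedule acquisition [echo_schedule()].
#' @param grid integer triple: voxels per sub-region block.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hs = 26L, n_oa = 26L,
                          age_mean = c(hs = 51.5, oa = 61.8),
                          age_sd = c(hs = 8.4, oa = 7.6),
                          age_range = c(40, 75),
                          female_prob = c(hs = 10 / 26, oa = 19 / 26),
                          bmi_mean = c(hs = 27.3, oa = 27.8),
                          bmi_sd = 3.5,
                          reference = be_reference(),
                          sd_scale = 1,
                          age_slope = NULL,
                          identical_groups = FALSE,
                          group_shift_sd = NULL,
                          amplitude = 100,
                          snr = 50,
                          schedule = default_pte_schedule(),
                          grid = c(8L, 8L, 2L)) {
  stopifnot(n_hs >= 1L, n_oa >= 1L, all(age_sd >= 0), bmi_sd >= 0,
            all(reference$sd >= 0), sd_scale >= 0, snr > 0,
            length(grid) == 3L, all(grid >= 1L))
  box <- model_box("be")
  med_ok <- vapply(seq_len(nrow(reference)), function(i) {
    p <- reference$param[i]
    reference$median[i] >= box$lower[[p]] && reference$median[i] <= box$upper[[p]]
  }, logical(1))
  if (!all(med_ok)) stop("reference medians must lie inside the BE box")
  structure(list(n_hs = as.integer(n_hs), n_oa = as.integer(n_oa),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 female_prob = female_prob, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, reference = reference,
                 sd_scale = sd_scale, age_slope = age_slope,
                 identical_groups = identical_groups,
                 group_shift_sd = group_shift_sd,
                 amplitude = amplitude, snr = snr,
                 schedule = as_echo_schedule(schedule),
                 grid = as.integer(grid)),
            class = "cohort_config")
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws covariates and per-subject latent sub-regional BE parameters, and —
#' when `output = "images"` — renders, per subject, a label map of six
#' sub-region blocks and the pTE-encoded complex image series with Gaussian
#' channel noise. Parameters drawn outside the BE box are truncated to it
#' and counted in the `n_truncated` attribute of `roi_truth`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; outputs are byte-identical under rerun.
#' @param output `"features"` (covariates + latent ROI parameters only;
#'   fast) or `"images"` (adds per-subject image series + label maps).
#' @return A list of class `t2oa_cohort`: `covariates` (`subject`, `group`,
#'   `age`, `sex`, `bmi`), `roi_truth` (long: `subject`, `roi` including
#'   `Global`, `f`, `t2_short`, `t2_long`), optionally `images` (per
#'   subject: `series`, `labels`), plus `config` and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            output = c("features", "images")) {
  stopifnot(inherits(config, "cohort_config"))
  output <- match.arg(output)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- config$n_hs + config$n_oa
  group <- rep(c(0L, 1L), c(config$n_hs, config$n_oa))
  # under the exact null the label is independent of *everything*, covariates
  # included: all draws then come from the HS distributions
  gname <- if (config$identical_groups) rep("hs", n) else
    ifelse(group == 1, "oa", "hs")
  age <- numeric(n)
  for (g in c("hs", "oa")) {
    sel <- gname == g
    age[sel] <- .rtrunc_norm(sum(sel), config$age_mean[[g]],
                             config$age_sd[[g]],
                             config$age_range[1], config$age_range[2])
  }
  covariates <- data.frame(
    subject = seq_len(n),
    group = group,
    age = age,
    sex = ifelse(stats::runif(n) < config$female_prob[gname], "F", "M"),
    bmi = stats::rnorm(n, unlist(config$bmi_mean[gname]), config$bmi_sd))

  rois <- names(roi_legend())
  params <- model_param_names("be")
  box <- model_box("be")
  ref <- config$reference
  n_trunc <- 0L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- if (config$identical_groups) "hs" else gname[i]
    vals <- matrix(NA_real_, length(rois), length(params),
                   dimnames = list(rois, params))
    for (r in rois) for (p in params) {
      rr <- ref[ref$group == g & ref$roi == r & ref$param == p, ]
      med <- rr$median
      sdv <- rr$sd * config$sd_scale
      if (group[i] == 1L && !is.null(config$group_shift_sd[[r]]) &&
          !is.na(config$group_shift_sd[[r]][p])) {
        med <- med + config$group_shift_sd[[r]][[p]] * sdv
      }
      if (!is.null(config$age_slope) && !is.na(config$age_slope[p])) {
        med <- med + config$age_slope[[p]] * (age[i] - 55)
      }
      x <- stats::rnorm(1, med, sdv)
      # keep strictly inside the box so be_params() accepts the draw
      eps <- 1e-6 * (box$upper[[p]] - box$lower[[p]])
      xt <- min(max(x, box$lower[[p]] + eps), box$upper[[p]] - eps)
      if (xt != x) n_trunc <- n_trunc + 1L
      vals[r, p] <- xt
    }
    rows[[i]] <- data.frame(subject = i, roi = c(rois, "Global"),
                            f = c(vals[, "f"], mean(vals[, "f"])),
                            t2_short = c(vals[, "t2_short"],
                                         mean(vals[, "t2_short"])),
                            t2_long = c(vals[, "t2_long"],
                                        mean(vals[, "t2_long"])))
  }
  roi_truth <- do.call(rbind, rows)
  attr(roi_truth, "n_truncated") <- n_trunc

  out <- list(covariates = covariates, roi_truth = roi_truth,
              config = config, seed = seed)
  if (output == "images") {
    sigma <- config$amplitude / config$snr
    g3 <- config$grid
    dims <- c(g3[1] * length(rois), g3[2], g3[3])
    nt <- length(config$schedule$ptes)
    labels <- array(0L, dims)
    for (k in seq_along(rois)) {
      labels[(k - 1) * g3[1] + seq_len(g3[1]), , ] <- roi_legend()[[rois[k]]]
    }
    out$images <- lapply(seq_len(n), function(i) {
      tr <- roi_truth[roi_truth$subject == i & roi_truth$roi != "Global", ]
      vox <- array(0i, c(dims, nt))
      for (k in seq_along(rois)) {
        pr <- be_params(config$amplitude, tr$f[k], tr$t2_short[k],
                        tr$t2_long[k])
        sig <- be_signal(pr, config$schedule)
        nvox <- prod(g3)
        block <- matrix(rep(sig, each = nvox), nvox, nt) +
          complex(real = stats::rnorm(nvox * nt, 0, sigma),
                  imaginary = stats::rnorm(nvox * nt, 0, sigma))
        xsel <- (k - 1) * g3[1] + seq_len(g3[1])
        vox[xsel, , , ] <- array(block, c(g3, nt))
      }
      list(series = image_series(vox, config$schedule), labels = labels)
    })
  }
  structure(out, class = "t2oa_cohort")
}

#' Generate an exact-null cohort
#'
#' Both groups are drawn from identical distributions (the HS reference) and
#' the group label is assigned independently of every feature: the null
#' backbone for calibrating the permutation and cross-validation machinery.
#'
#' @inheritParams generate_cohort
#' @return A `t2oa_cohort`, as [generate_cohort()].
#' @export
generate_null_cohort <- function(config = cohort_config(), seed = 1L,
                                 output = c("features", "images")) {
  config$identical_groups <- TRUE
  config$group_shift_sd <- NULL
  generate_cohort(config, seed, output)
}

#' Latent-parameter feature table of a cohort
#'
#' Feature table built directly from the latent (noise-free) sub-regional
#' parameters — the measurement a perfect fitting stage would deliver.
#'
#' @param cohort a `t2oa_cohort`.
#' @param scope `"multi"` or `"global"`.
#' @return A feature table as from [build_feature_table()].
#' @export
cohort_true_features <- function(cohort, scope = c("multi", "global")) {
  build_feature_table(cohort$roi_truth, cohort$covariates, "be",
                      match.arg(scope))
}

#' Fit a cohort's image series and assemble measured features
#'
#' The imaging arm of the pipeline: per subject, fits the requested model
#' over the labeled voxels, extracts valid-voxel ROI means and builds the
#' feature table.
#'
#' @param cohort a `t2oa_cohort` generated with `output = "images"`.
#' @param model `"me"`, `"be"` or `"se"`.
#' @param scope `"multi"` or `"global"`.
#' @param config a [fit_config()].
#' @return A feature table as from [build_feature_table()].
#' @export
fit_cohort_features <- function(cohort, model = "be",
                                scope = c("multi", "global"),
                                config = fit_config()) {
  stopifnot(inherits(cohort, "t2oa_cohort"))
  if (is.null(cohort$images)) stop("cohort was generated without images")
  scope <- match.arg(scope)
  long <- do.call(rbind, lapply(seq_along(cohort$images), function(i) {
    im <- cohort$images[[i]]
    pm <- fit_map(im$series, im$labels > 0, model, config)
    rm <- extract_roi_means(pm, im$labels)
    rm$subject <- cohort$covariates$subject[i]
    rm
  }))
  build_feature_table(long, cohort$covariates, model, scope)
}
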