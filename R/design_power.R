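## Study design arithmetic: the two-sample power calculation and protocol
## timing.

#' Sample size for a two-sample comparison of means
#'
#' Smallest per-group `n` achieving the requested power for a two-tailed
#' two-sample t test where the detectable difference is a fraction of the
#' reference mean (`delta = detectable_fraction * mean`). Power is evaluated
#' with the exact noncentral-t function (via [stats::power.t.test()]); the
#' normal approximation undershoots at the sample sizes this design
#' question lives at.
#'
#' @param mean reference group mean (e.g. global T2 in ms).
#' @param sd common standard deviation (same units), `> 0`.
#' @param detectable_fraction minimum detectable effect as a fraction of
#'   `mean`, in (0, 1).
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @param n_max search cap.
#' @return Integer `n` per group, with the achieved power as attribute
#'   `"power"`.
#' @examples
#' sample_size_two_means(34, 2.6, 0.07)  # 20 per group
#' @export
sample_size_two_means <- function(mean, sd, detectable_fraction,
                                  alpha = 0.05, power = 0.80,
                                  n_max = 1e5L) {
  stopifnot(sd > 0, detectable_fraction > 0, detectable_fraction < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  delta <- detectable_fraction * mean
  for (n in 2:n_max) {
    pw <- stats::power.t.test(n = n, delta = delta, sd = sd,
                              sig.level = alpha,
                              type = "two.sample",
                              alternative = "two.sided")$power
    if (pw >= power) {
      return(structure(as.integer(n), power = pw))
    }
  }
  stop("requested power not achievable within 'n_max' subjects per group")
}

#' Total acquisition time of a multi-image protocol
#'
#' @param n_images number of weighted images acquired.
#' @param per_image_min,per_image_sec scan time of one image.
#' @return List: `total_seconds`, `minutes`, `seconds`, and a formatted
#'   `label` (e.g. `"22 min 24 s"`).
#' @examples
#' total_scan_time(7, 3, 12)  # 22 min 24 s
#' @export
total_scan_time <- function(n_images, per_image_min = 3, per_image_sec = 12) {
  stopifnot(n_images >= 1, per_image_min >= 0, per_image_sec >= 0)
  tot <- n_images * (60 * per_image_min + per_image_sec)
  list(total_seconds = tot,
       minutes = tot %/% 60,
       seconds = tot %% 60,
       label = sprintf("%d min %d s", tot %/% 60, tot %% 60))
}
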