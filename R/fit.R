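## Bounded nonlinear least-squares fitting of single-voxel complex decays.

#' Fitting configuration
#'
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param tol gradient/step tolerance passed to the optimizer (`ftol` and
#'   `ptol`).
#' @param starts optional matrix of nonlinear-parameter starting points (one
#'   row per start, columns in [model_param_names()] order); defaults to the
#'   model's deterministic coarse grid, see [default_starts()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iter = 500L, tol = 1e-10, starts = NULL) {
  structure(list(max_iter = as.integer(max_iter), tol = tol, starts = starts),
            class = "fit_config")
}

#' Deterministic multi-start initialization grids
#'
#' Starting points spanning each model's box: ME and SE start `t2` at
#' \{5, 20, 50, 150\} ms and SE `alpha` at \{0.4, 0.7, 1.0\}; BE starts `f`
#' at \{0.1, 0.3, 0.5\}, `t2_short` at \{2, 6\} ms and `t2_long` at
#' \{40, 120\} ms. Amplitude starts are profiled from the data (linear least
#' squares given the decay shape), so only nonlinear parameters are gridded.
#'
#' @param model `"me"`, `"be"` or `"se"`.
#' @return Matrix with one start per row.
#' @export
default_starts <- function(model) {
  switch(model_id(model),
         me = cbind(t2 = c(5, 20, 50, 150)),
         se = as.matrix(expand.grid(t2 = c(5, 20, 50, 150),
                                    alpha = c(0.4, 0.7, 1.0))),
         be = as.matrix(expand.grid(f = c(0.1, 0.3, 0.5),
                                    t2_short = c(2, 6),
                                    t2_long = c(40, 120))))
}

## residuals/Jacobian for nls.lm on p = (ReA, ImA, theta); y split as (yr, yi)
.fit_resid <- function(p, model, t, yr, yi) {
  g <- .decay(model, p[-(1:2)], t)
  c(p[1L] * g - yr, p[2L] * g - yi)
}

.fit_jac <- function(p, model, t, yr, yi) {
  g <- .decay(model, p[-(1:2)], t)
  G <- .decay_grad(model, p[-(1:2)], t)
  z <- numeric(length(t))
  rbind(cbind(g, z, p[1L] * G),
        cbind(z, g, p[2L] * G))
}

#' Fit one voxel's complex decay
#'
#' Minimizes the sum of squared complex residuals (real and imaginary
#' channels stacked) over `(Re A, Im A, theta)` subject to the model's box
#' constraints, by bounded Levenberg-Marquardt from every start in a
#' deterministic coarse grid; the best start wins. Repeated pTEs enter as
#' separate residual terms — no pre-averaging.
#'
#' A voxel where no start converges, or whose signal is identically zero, is
#' returned flagged (`converged = FALSE`) rather than raising an error, so
#' map-level fitting can continue.
#'
#' @param signal complex vector, one entry per pTE.
#' @param schedule matching [echo_schedule()].
#' @param model `"me"`, `"be"` or `"se"`.
#' @param config a [fit_config()].
#' @return A list of class `fit_result`: `model`, `A` (complex), `theta`
#'   (named nonlinear parameters), `residual_norm`, `converged`,
#'   `n_starts_used`, and `start_residuals` (residual norm at each
#'   initialization point, before optimization).
#' @export
fit_voxel <- function(signal, schedule, model, config = fit_config()) {
  schedule <- as_echo_schedule(schedule)
  model <- model_id(model)
  t <- schedule$ptes
  if (length(signal) != length(t)) {
    stop(sprintf("signal length %d != schedule length %d",
                 length(signal), length(t)))
  }
  box <- model_box(model)
  n_free <- 2L + length(box$lower)
  if (2L * length(t) < n_free) stop("fewer observations than free parameters")
  yr <- Re(signal); yi <- Im(signal)
  if (!all(is.finite(yr)) || !all(is.finite(yi))) stop("non-finite signal")

  empty <- function() {
    structure(list(model = model, A = NA_complex_,
                   theta = stats::setNames(rep(NA_real_, length(box$lower)),
                                           names(box$lower)),
                   residual_norm = NA_real_, converged = FALSE,
                   n_starts_used = 0L, start_residuals = numeric(0)),
              class = "fit_result")
  }
  if (all(yr == 0) && all(yi == 0)) return(empty())

  starts <- if (is.null(config$starts)) default_starts(model) else config$starts
  lower <- c(-Inf, -Inf, box$lower)
  upper <- c(Inf, Inf, box$upper)
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                     ftol = config$tol, ptol = config$tol)
  best <- NULL
  best_dev <- Inf
  start_res <- numeric(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    theta0 <- as.numeric(starts[s, ])
    g0 <- .decay(model, theta0, t)
    gg <- sum(g0 * g0)
    a0 <- if (gg > 0) c(sum(g0 * yr), sum(g0 * yi)) / gg else c(yr[1L], yi[1L])
    p0 <- c(a0, theta0)
    start_res[s] <- sqrt(sum(.fit_resid(p0, model, t, yr, yi)^2))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = .fit_resid, jac = .fit_jac,
                         model = model, t = t, yr = yr, yi = yi,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$deviance < best_dev) {
      best <- fit
      best_dev <- fit$deviance
    }
  }
  if (is.null(best)) {
    out <- empty()
    out$n_starts_used <- nrow(starts)
    out$start_residuals <- start_res
    return(out)
  }
  p <- best$par
  theta <- stats::setNames(pmin(pmax(p[-(1:2)], box$lower), box$upper),
                           names(box$lower))
  structure(list(model = model,
                 A = complex(real = p[1L], imaginary = p[2L]),
                 theta = theta,
                 residual_norm = sqrt(best$deviance),
                 converged = best$info %in% 1:4,  # MINPACK success codes
                 n_starts_used = nrow(starts),
                 start_residuals = start_res),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: |A| = %.4g, %s, residual = %.4g (%s)\n",
              x$model, Mod(x$A),
              paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                    collapse = ", "),
              x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
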