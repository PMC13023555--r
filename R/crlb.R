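## Experiment design: Fisher information and Cramer-Rao lower bounds for the
## complex Gaussian noise model, and pTE-schedule optimization.

## Real parameterization (Re A, Im A, theta_model); matches the complex-valued
## fitting downstream. Since g(t) is real, the stacked real/imaginary Jacobian
## has a simple block structure.
.fisher_information <- function(model, A, theta, ptes, sigma) {
  g <- .decay(model, theta, ptes)
  G <- .decay_grad(model, theta, ptes)
  # complex Jacobian columns: dS/dReA = g, dS/dImA = i g, dS/dtheta_j = A G_j
  Jr <- cbind(g, 0, Re(A) * G)         # real channel
  Ji <- cbind(0, g, Im(A) * G)         # imaginary channel
  fim <- (crossprod(Jr) + crossprod(Ji)) / sigma^2
  dimnames(fim) <- rep(list(c("re_a", "im_a", colnames(G))), 2L)
  fim
}

#' Cramer-Rao lower bounds for a pTE schedule
#'
#' Computes, for a given relaxation model, nominal parameter values,
#' acquisition schedule and per-channel noise level, the minimum achievable
#' estimator variance for each real parameter: the diagonal of the inverse
#' Fisher information under i.i.d. complex Gaussian noise. The real
#' parameterization is `(Re A, Im A, theta_model)`. Bounds scale exactly as
#' `sigma^2`.
#'
#' A schedule that cannot identify the parameters (for example, all pTEs
#' equal) has a singular information matrix and is reported as a design
#' failure rather than being silently inverted.
#'
#' @param params a [model_params] record providing the nominal values.
#' @param schedule an [echo_schedule()] or numeric vector (ms).
#' @param sigma per-channel noise standard deviation, `> 0`.
#' @return Named numeric vector of variance lower bounds
#'   (`re_a`, `im_a`, then the model parameters).
#' @export
crlb <- function(params, schedule, sigma) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single number > 0")
  }
  schedule <- as_echo_schedule(schedule)
  m <- model_id(params)
  theta <- unlist(params[model_param_names(m)])
  fim <- .fisher_information(m, params$A, theta, schedule$ptes, sigma)
  if (!all(is.finite(fim)) || rcond(fim) < 1e-13) {
    stop("design failure: singular Fisher information for this schedule")
  }
  bounds <- diag(solve(fim))
  names(bounds) <- colnames(fim)
  bounds
}

## Normalized design objective: sum over parameters of CRLB_i / ref_i^2,
## ref = (|A|, |A|, |theta|). Infinite for non-identifying schedules.
.design_objective <- function(model, A, theta, ref2, ptes, sigma, weights) {
  fim <- .fisher_information(model, A, theta, ptes, sigma)
  if (!all(is.finite(fim)) || rcond(fim) < 1e-13) return(Inf)
  sum(weights * diag(solve(fim)) / ref2)
}

#' Optimize a preparation-time schedule by the CRLB criterion
#'
#' Chooses `n_images` preparation times (repeats allowed) from a grid so as
#' to minimize the normalized sum of Cramer-Rao bounds
#' `sum_i w_i CRLB_i / ref_i^2`, with `ref = (|A|, |A|, |theta|)` at the
#' nominal parameter values. The nominal tissue parameters and the
#' per-parameter weights are explicit inputs: schedule design depends on the
#' tissue one designs for.
#'
#' Small problems are solved by exhaustive enumeration of all multisets;
#' larger grids use a deterministic greedy exchange (coordinate-wise best
#' replacement until no single swap improves the objective). The strategy
#' used is recorded in the result's `"design"` attribute.
#'
#' @param params nominal [model_params] for the tissue of interest.
#' @param n_images number of acquisitions; must be at least the number of
#'   free real parameters.
#' @param grid candidate pTEs (ms), e.g. `seq(0.1, 55, by = 0.1)`.
#' @param sigma per-channel noise sd (any `> 0`; the argmin is
#'   sigma-invariant).
#' @param weights optional per-parameter weights (length 2 + number of model
#'   parameters); default all 1.
#' @param method `"auto"` (default), `"exhaustive"` or `"greedy"`.
#' @param max_exhaustive multiset-count cap under which `"auto"` enumerates.
#' @return An [echo_schedule()] (sorted increasing) with attribute
#'   `"design"`: a list with `method`, `objective`, `n_evaluated`.
#' @export
optimize_schedule <- function(params, n_images, grid, sigma = 1,
                              weights = NULL,
                              method = c("auto", "exhaustive", "greedy"),
                              max_exhaustive = 2e5) {
  stopifnot(inherits(params, "model_params"))
  method <- match.arg(method)
  m <- model_id(params)
  theta <- unlist(params[model_param_names(m)])
  # each image contributes a real and an imaginary sample, so the complex
  # amplitude counts once against the image budget
  p_free <- 1L + length(theta)
  if (n_images < p_free) {
    stop(sprintf("infeasible design: %d images for %d free parameters",
                 n_images, p_free))
  }
  p_free <- p_free + 1L  # real parameterization size for weights/ref
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid < 0)) stop("grid times must be >= 0")
  if (is.null(weights)) weights <- rep(1, p_free)
  stopifnot(length(weights) == p_free, all(weights >= 0))
  ref2 <- c(Mod(params$A), Mod(params$A), abs(theta))^2
  obj <- function(ptes) .design_objective(m, params$A, theta, ref2, ptes,
                                          sigma, weights)

  n_multisets <- choose(length(grid) + n_images - 1, n_images)
  if (method == "auto") {
    method <- if (n_multisets <= max_exhaustive) "exhaustive" else "greedy"
  }

  if (method == "exhaustive") {
    combos <- utils::combn(length(grid) + n_images - 1, n_images)
    # multisets via stars-and-bars: subtract 0:(n-1) to map combinations to
    # non-decreasing index tuples
    idx <- combos - (seq_len(n_images) - 1L)
    vals <- apply(idx, 2L, function(i) obj(grid[i]))
    best <- which.min(vals)
    ptes <- grid[idx[, best]]
    meta <- list(method = "exhaustive", objective = vals[best],
                 n_evaluated = ncol(idx))
  } else {
    # deterministic start: evenly spaced quantiles of the grid
    ptes <- grid[unique(round(seq(1, length(grid), length.out = n_images)))]
    ptes <- rep(ptes, length.out = n_images)
    cur <- obj(ptes)
    n_eval <- 1L
    for (sweep in seq_len(50L)) {
      improved <- FALSE
      for (k in seq_len(n_images)) {
        cand <- vapply(grid, function(g) {
          trial <- ptes; trial[k] <- g; obj(trial)
        }, numeric(1))
        n_eval <- n_eval + length(grid)
        if (min(cand) < cur - 1e-12 * abs(cur)) {
          ptes[k] <- grid[which.min(cand)]
          cur <- min(cand)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    meta <- list(method = "greedy", objective = cur, n_evaluated = n_eval)
  }
  if (!is.finite(meta$objective)) {
    stop("design failure: no identifying schedule found on this grid")
  }
  out <- echo_schedule(sort(ptes),
                       grid_step = if (length(grid) > 1) min(diff(grid)) else 0.1)
  attr(out, "design") <- meta
  out
}
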