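#' Relaxation model parameter records
#'
#' Three competing voxel decay models are supported, each with the box
#' constraints used for fitting:
#' \describe{
#'   \item{mono-exponential (`me`)}{`S(t) = A exp(-t / t2)`, `t2` in
#'     \[0.1, 400\] ms.}
#'   \item{bi-exponential (`be`)}{`S(t) = A (f exp(-t / t2_short) +
#'     (1 - f) exp(-t / t2_long))`; `f` in \[0.01, 0.99\] is the fraction of
#'     the fast-relaxing (macromolecule-bound) water pool, `t2_short` in
#'     \[0.1, 10\] ms, `t2_long` in \[20, 300\] ms. The disjoint boxes keep
#'     the two pools identifiable without post-hoc sorting.}
#'   \item{stretched-exponential (`se`)}{`S(t) = A exp(-(t / t2)^alpha)`;
#'     `alpha` in \[0.1, 1.0\] parameterizes relaxation-time heterogeneity,
#'     `alpha = 1` recovering the mono-exponential model.}
#' }
#' `A` is the complex signal amplitude (real inputs are promoted), with
#' `|A| > 0`.
#'
#' @param A complex (or real) signal amplitude, `|A| > 0`.
#' @param t2 relaxation time in ms.
#' @param f short-pool fraction.
#' @param t2_short,t2_long short/long pool relaxation times in ms.
#' @param alpha stretching exponent.
#' @return A parameter record of class `me_params`, `be_params` or
#'   `se_params` (all inheriting from `model_params`).
#' @name model_params
NULL

.check_amp <- function(A) {
  A <- as.complex(A)
  if (length(A) != 1L || !is.finite(Re(A)) || !is.finite(Im(A)) || Mod(A) <= 0) {
    stop("amplitude 'A' must be a single finite complex value with |A| > 0")
  }
  A
}

.check_box <- function(value, name, lo, hi) {
  if (length(value) != 1L || !is.finite(value)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (value < lo || value > hi) {
    stop(sprintf("'%s' = %g outside [%g, %g]", name, value, lo, hi))
  }
  as.numeric(value)
}

#' @rdname model_params
#' @export
me_params <- function(A, t2) {
  structure(list(A = .check_amp(A), t2 = .check_box(t2, "t2", 0.1, 400)),
            class = c("me_params", "model_params"))
}

#' @rdname model_params
#' @export
be_params <- function(A, f, t2_short, t2_long) {
  t2_short <- .check_box(t2_short, "t2_short", 0.1, 10)
  t2_long <- .check_box(t2_long, "t2_long", 20, 300)
  if (t2_short >= t2_long) stop("'t2_short' must be smaller than 't2_long'")
  structure(list(A = .check_amp(A), f = .check_box(f, "f", 0.01, 0.99),
                 t2_short = t2_short, t2_long = t2_long),
            class = c("be_params", "model_params"))
}

#' @rdname model_params
#' @export
se_params <- function(A, t2, alpha) {
  structure(list(A = .check_amp(A), t2 = .check_box(t2, "t2", 0.1, 400),
                 alpha = .check_box(alpha, "alpha", 0.1, 1.0)),
            class = c("se_params", "model_params"))
}

#' @export
print.model_params <- function(x, ...) {
  cat(model_id(x), "params: A =", format(x$A), "|",
      paste(sprintf("%s = %g", model_param_names(model_id(x)),
                    unlist(x[model_param_names(model_id(x))])),
            collapse = ", "), "\n")
  invisible(x)
}

#' Model identifiers and parameter vocabulary
#'
#' @param x a `model_params` record, or a model id string.
#' @return `model_id` returns one of `"me"`, `"be"`, `"se"`;
#'   `model_param_names` the nonlinear parameter names in canonical order;
#'   `model_box` a list with `lower` and `upper` named bounds.
#' @export
model_id <- function(x) {
  if (is.character(x)) return(match.arg(x, c("me", "be", "se")))
  switch(class(x)[1L],
         me_params = "me", be_params = "be", se_params = "se",
         stop("not a model_params record"))
}

#' @rdname model_id
#' @export
model_param_names <- function(x) {
  switch(model_id(x),
         me = "t2",
         se = c("t2", "alpha"),
         be = c("f", "t2_short", "t2_long"))
}

#' @rdname model_id
#' @export
model_box <- function(x) {
  switch(model_id(x),
         me = list(lower = c(t2 = 0.1), upper = c(t2 = 400)),
         se = list(lower = c(t2 = 0.1, alpha = 0.1),
                   upper = c(t2 = 400, alpha = 1.0)),
         be = list(lower = c(f = 0.01, t2_short = 0.1, t2_long = 20),
                   upper = c(f = 0.99, t2_short = 10, t2_long = 300)))
}

## Unit-amplitude decay g(t; theta) and its gradient. g is real for all three
## models, so S = A g and the real/imaginary channels share the same shape.
.decay <- function(model, theta, t) {
  switch(model,
    me = exp(-t / theta[[1L]]),
    se = {
      u <- ifelse(t > 0, (t / theta[[1L]])^theta[[2L]], 0)  # 0^alpha := 0
      exp(-u)
    },
    be = theta[[1L]] * exp(-t / theta[[2L]]) +
      (1 - theta[[1L]]) * exp(-t / theta[[3L]]))
}

.decay_grad <- function(model, theta, t) {
  switch(model,
    me = {
      g <- exp(-t / theta[[1L]])
      cbind(t2 = g * t / theta[[1L]]^2)
    },
    se = {
      t2 <- theta[[1L]]; alpha <- theta[[2L]]
      u <- ifelse(t > 0, (t / t2)^alpha, 0)
      g <- exp(-u)
      dlog <- ifelse(t > 0, log(t / t2), 0)
      cbind(t2 = g * alpha * u / t2, alpha = -g * u * dlog)
    },
    be = {
      f <- theta[[1L]]; ts <- theta[[2L]]; tl <- theta[[3L]]
      es <- exp(-t / ts); el <- exp(-t / tl)
      cbind(f = es - el,
            t2_short = f * es * t / ts^2,
            t2_long = (1 - f) * el * t / tl^2)
    })
}

.signal <- function(params, schedule) {
  schedule <- as_echo_schedule(schedule)
  m <- model_id(params)
  theta <- unlist(params[model_param_names(m)])
  params$A * .decay(m, theta, schedule$ptes)
}

#' Forward relaxation signals
#'
#' Noise-free complex decay curves evaluated at the schedule's preparation
#' times. `se_signal` defines `0^alpha = 0` so the signal at `t = 0` is
#' exactly `A` for every `alpha`.
#'
#' @param params a matching parameter record ([me_params()], [be_params()],
#'   [se_params()]).
#' @param schedule an [echo_schedule()] or numeric vector of pTEs (ms).
#' @return Complex vector with one entry per pTE.
#' @examples
#' me_signal(me_params(100, 40), c(0, 40))     # 100, 100 * exp(-1)
#' @export
me_signal <- function(params, schedule) {
  stopifnot(inherits(params, "me_params"))
  .signal(params, schedule)
}

#' @rdname me_signal
#' @export
be_signal <- function(params, schedule) {
  stopifnot(inherits(params, "be_params"))
  .signal(params, schedule)
}

#' @rdname me_signal
#' @export
se_signal <- function(params, schedule) {
  stopifnot(inherits(params, "se_params"))
  .signal(params, schedule)
}

#' Add complex Gaussian acquisition noise
#'
#' Adds independent zero-mean Gaussian noise with standard deviation `sigma`
#' to the real and imaginary channels. The two channels are i.i.d. (no
#' channel correlation is modeled).
#'
#' @param signal complex vector.
#' @param sigma per-channel noise standard deviation (signal units), `>= 0`.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Complex vector of the same length.
#' @export
add_complex_noise <- function(signal, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("'sigma' must be a single number >= 0")
  }
  if (sigma == 0) return(signal)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(signal)
  signal + complex(real = stats::rnorm(n, 0, sigma),
                   imaginary = stats::rnorm(n, 0, sigma))
}
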