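#' Preparation-time (pTE) schedules
#'
#' An `echo_schedule` holds the vector of T2-preparation times (pTE, also
#' called TSL) at which weighted volumes are acquired, in milliseconds.
#' Duplicate entries are allowed and meaningful: a repeated pTE is acquired
#' twice and contributes two independent noisy samples to the likelihood,
#' which is how repeat acquisitions boost SNR at long preparation times.
#'
#' @param ptes numeric vector of preparation times in ms, all `>= 0`.
#' @param grid_step grid resolution (ms) used when the schedule takes part in
#'   a design search; defaults to 0.1 ms.
#' @return An object of class `echo_schedule`.
#' @seealso [optimize_schedule()], [default_pte_schedule()]
#' @export
echo_schedule <- function(ptes, grid_step = 0.1) {
  ptes <- as.numeric(ptes)
  if (length(ptes) < 1L || any(!is.finite(ptes)) || any(ptes < 0)) {
    stop("'ptes' must be a non-empty vector of finite times >= 0 (ms)")
  }
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0) {
    stop("'grid_step' must be a single positive number (ms)")
  }
  structure(list(ptes = ptes, grid_step = grid_step), class = "echo_schedule")
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat("pTE schedule (ms):", paste(format(x$ptes), collapse = ", "), "\n")
  invisible(x)
}

#' Coerce to an echo schedule
#'
#' Plain numeric vectors are accepted anywhere a schedule is expected.
#' @param x an `echo_schedule` or numeric vector of pTEs (ms).
#' @return An `echo_schedule`.
#' @export
as_echo_schedule <- function(x) {
  if (inherits(x, "echo_schedule")) return(x)
  echo_schedule(x)
}

#' The 7-point preparation-time schedule used throughout
#'
#' The CRLB-optimized acquisition schedule \{0, 4.3, 9, 33, 33, 55, 55\} ms,
#' with the 33 and 55 ms preparations each acquired twice. This is the
#' default acquisition protocol assumed by the synthetic cohort generator.
#'
#' @return An `echo_schedule` with 7 entries.
#' @export
default_pte_schedule <- function() {
  echo_schedule(c(0, 4.3, 9, 33, 33, 55, 55))
}

#' Read / write a pTE schedule as JSON
#'
#' Schedules serialize as a bare JSON array of times in ms.
#' @param schedule an `echo_schedule` (or numeric vector).
#' @param path file path.
#' @return `read_schedule` returns an `echo_schedule`; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- as_echo_schedule(schedule)
  jsonlite::write_json(schedule$ptes, path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  echo_schedule(jsonlite::fromJSON(path))
}
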