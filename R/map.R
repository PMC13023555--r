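## Image-series container and map-level fitting.

#' A preparation-time-encoded image series
#'
#' @param voxels 4D complex array `(x, y, z, echo)`.
#' @param schedule matching [echo_schedule()]; its length must equal the
#'   echo dimension.
#' @param voxel_size numeric triple (mm).
#' @return An object of class `image_series`.
#' @export
image_series <- function(voxels, schedule, voxel_size = c(1, 1, 1)) {
  schedule <- as_echo_schedule(schedule)
  if (length(dim(voxels)) != 4L) stop("'voxels' must be a 4D array")
  if (dim(voxels)[4L] != length(schedule$ptes)) {
    stop(sprintf("echo dimension (%d) != schedule length (%d)",
                 dim(voxels)[4L], length(schedule$ptes)))
  }
  if (!is.complex(voxels)) voxels <- voxels + 0i
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(voxels = voxels, schedule = schedule,
                 voxel_size = as.numeric(voxel_size)),
            class = "image_series")
}

#' Fit a relaxation model over a masked volume
#'
#' Applies [fit_voxel()] to every voxel inside `mask` and assembles 3D
#' parameter maps. Results are independent of voxel visiting order. Voxels
#' outside the mask are `NA`; non-converged voxels keep their best-fit values
#' but are flagged in the `converged` volume so downstream ROI averaging can
#' exclude them.
#'
#' @param series an [image_series()].
#' @param mask logical (or 0/1) 3D array on the same grid.
#' @param model `"me"`, `"be"` or `"se"`.
#' @param config a [fit_config()].
#' @return A `parameter_map`: list with `model`, `values` (named list of 3D
#'   arrays: `a_mod`, the model parameters, `residual`), `converged`
#'   (logical 3D array), `schedule`, `voxel_size`, `dim`.
#' @export
fit_map <- function(series, mask, model, config = fit_config()) {
  stopifnot(inherits(series, "image_series"))
  model <- model_id(model)
  dims <- dim(series$voxels)[1:3]
  mask <- array(as.logical(mask), dim = dims)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  pnames <- model_param_names(model)
  values <- c(list(a_mod = array(NA_real_, dims)),
              stats::setNames(replicate(length(pnames),
                                        array(NA_real_, dims),
                                        simplify = FALSE), pnames),
              list(residual = array(NA_real_, dims)))
  converged <- array(NA, dims)
  nt <- dim(series$voxels)[4L]
  flat <- matrix(series$voxels, ncol = nt)
  for (v in idx) {
    fit <- fit_voxel(flat[v, ], series$schedule, model, config)
    values$a_mod[v] <- Mod(fit$A)
    for (p in pnames) values[[p]][v] <- fit$theta[[p]]
    values$residual[v] <- fit$residual_norm
    converged[v] <- fit$converged
  }
  structure(list(model = model, values = values, converged = converged,
                 schedule = series$schedule, voxel_size = series$voxel_size,
                 dim = dims),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("%s parameter map, grid %s, %d fitted voxels (%d converged)\n",
              x$model, paste(x$dim, collapse = "x"),
              sum(!is.na(x$converged)), sum(x$converged, na.rm = TRUE)))
  invisible(x)
}
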