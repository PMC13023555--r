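## NIfTI-1 I/O. Complex series are stored as paired real/imaginary volumes
## with a JSON sidecar carrying the schedule and grid metadata.

.sidecar_path <- function(prefix) paste0(prefix, ".json")

#' Write / read a complex image series
#'
#' `write_image_series` stores `<prefix>_real.nii` and `<prefix>_imag.nii`
#' (4D float volumes) plus `<prefix>.json` holding the pTE schedule and
#' voxel size. `read_image_series` reverses it.
#'
#' @param series an [image_series()].
#' @param prefix path prefix (no extension).
#' @return `write_image_series` returns `prefix` invisibly;
#'   `read_image_series` an [image_series()].
#' @export
write_image_series <- function(series, prefix) {
  stopifnot(inherits(series, "image_series"))
  RNifti::writeNifti(RNifti::asNifti(Re(series$voxels),
                                     pixdim = series$voxel_size),
                     paste0(prefix, "_real.nii"))
  RNifti::writeNifti(RNifti::asNifti(Im(series$voxels),
                                     pixdim = series$voxel_size),
                     paste0(prefix, "_imag.nii"))
  jsonlite::write_json(list(ptes = series$schedule$ptes,
                            grid_step = series$schedule$grid_step,
                            voxel_size = series$voxel_size),
                       .sidecar_path(prefix), digits = NA, auto_unbox = FALSE)
  invisible(prefix)
}

#' @rdname write_image_series
#' @export
read_image_series <- function(prefix) {
  meta <- jsonlite::fromJSON(.sidecar_path(prefix))
  re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii")))
  im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii")))
  vox <- array(complex(real = re, imaginary = im), dim = dim(re))
  if (dim(vox)[4L] != length(meta$ptes)) {
    stop(sprintf("echo count %d does not match schedule length %d",
                 dim(vox)[4L], length(meta$ptes)))
  }
  image_series(vox, echo_schedule(meta$ptes, meta$grid_step),
               voxel_size = meta$voxel_size)
}

#' Write / read a sub-region label map
#'
#' Integer NIfTI volume plus a JSON sidecar with the label legend
#' ([roi_legend()]).
#'
#' @param labels integer 3D array.
#' @param path `.nii` path (sidecar written next to it).
#' @return `read_label_map` returns the integer array with the legend as
#'   attribute `"legend"`.
#' @export
write_label_map <- function(labels, path) {
  storage.mode(labels) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(labels, datatype = "int16"), path)
  jsonlite::write_json(as.list(roi_legend()),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "integer"
  legend_path <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(legend_path)) {
    attr(arr, "legend") <- unlist(jsonlite::fromJSON(legend_path))
  }
  arr
}

#' Write a parameter map to a directory
#'
#' One float32 NIfTI per parameter volume (plus residual and convergence
#' mask) and a JSON sidecar recording the model, its box constraints, the
#' schedule and the grid.
#'
#' @param pm a `parameter_map` from [fit_map()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_parameter_maps <- function(pm, dir) {
  stopifnot(inherits(pm, "parameter_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(pm$values)) {
    RNifti::writeNifti(RNifti::asNifti(pm$values[[nm]],
                                       pixdim = pm$voxel_size,
                                       datatype = "float"),
                       file.path(dir, paste0(nm, ".nii")))
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(pm$converged), pm$dim),
                                     datatype = "int16"),
                     file.path(dir, "converged.nii"))
  box <- model_box(pm$model)
  jsonlite::write_json(list(model = pm$model,
                            parameters = names(pm$values),
                            lower = as.list(box$lower),
                            upper = as.list(box$upper),
                            ptes = pm$schedule$ptes,
                            voxel_size = pm$voxel_size,
                            dim = pm$dim),
                       file.path(dir, "map.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Check that two volumes share a grid
#'
#' @param a,b arrays (or objects with a `dim` field).
#' @return Invisibly `TRUE`; otherwise an error naming both shapes.
#' @export
check_same_grid <- function(a, b) {
  da <- if (!is.null(dim(a))) dim(a)[1:3] else a$dim
  db <- if (!is.null(dim(b))) dim(b)[1:3] else b$dim
  if (!identical(as.integer(da), as.integer(db))) {
    stop(sprintf("grid mismatch: [%s] vs [%s]",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}
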