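## Sub-regional cartilage feature extraction.

#' Cartilage sub-region legend
#'
#' Integer encoding of the six QIBA-style knee cartilage sub-regions used
#' throughout: patellar (PC), trochlear (TrC), medial femoral (MFC), medial
#' tibial (MTC), lateral femoral (LFC) and lateral tibial (LTC) cartilage;
#' 0 is background. The encoding is this package's convention and is written
#' into label-map sidecars and feature CSV headers.
#'
#' @return Named integer vector `c(PC = 1, TrC = 2, MFC = 3, MTC = 4,
#'   LFC = 5, LTC = 6)`.
#' @export
roi_legend <- function() {
  c(PC = 1L, TrC = 2L, MFC = 3L, MTC = 4L, LFC = 5L, LTC = 6L)
}

#' Per-ROI mean parameter extraction
#'
#' Averages each parameter map over the voxels of each labeled sub-region,
#' using only valid voxels (converged fits; values inside the model box by
#' construction). The `Global` row is the mean over the union of all six
#' labels — voxel-weighted, not a mean of ROI means, so large regions count
#' proportionally to their size.
#'
#' @param map a `parameter_map` from [fit_map()], or a named list of 3D
#'   arrays (then `converged` is taken as all-true).
#' @param labels integer 3D array with values in 0..6 on the same grid (see
#'   [roi_legend()]).
#' @return `data.frame` with columns `roi`, `n_voxels`, then one column per
#'   parameter. Rows: PC, TrC, MFC, MTC, LFC, LTC, Global. Empty ROIs give
#'   `NA` with a warning.
#' @export
extract_roi_means <- function(map, labels) {
  if (inherits(map, "parameter_map")) {
    values <- map$values[c(model_param_names(map$model))]
    ok <- !is.na(map$converged) & map$converged
    dims <- map$dim
  } else {
    values <- map
    dims <- dim(values[[1L]])
    ok <- array(TRUE, dims)
  }
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!identical(dim(labels), dims)) {
    stop(sprintf("label grid [%s] does not match map grid [%s]",
                 paste(dim(labels), collapse = "x"),
                 paste(dims, collapse = "x")))
  }
  legend <- roi_legend()
  rois <- c(names(legend), "Global")
  out <- data.frame(roi = rois, n_voxels = 0L)
  for (p in names(values)) out[[p]] <- NA_real_
  for (i in seq_along(rois)) {
    sel <- if (rois[i] == "Global") labels %in% legend else labels == legend[[rois[i]]]
    sel <- sel & ok
    out$n_voxels[i] <- sum(sel)
    if (!any(sel)) {
      warning(sprintf("ROI %s has no valid voxels", rois[i]))
      next
    }
    for (p in names(values)) out[[p]][i] <- mean(values[[p]][sel])
  }
  out
}

#' Assemble the subjects-by-features table
#'
#' Builds the classifier input: one row per subject, feature columns named
#' `<param>_<ROI>` in parameter-major order with ROIs ordered PC, TrC, MFC,
#' MTC, LFC, LTC (`scope = "multi"`) or a single `<param>_Global` column per
#' parameter (`scope = "global"`). Feature counts are 1/2/3 (global) and
#' 6/12/18 (multi-ROI) for the ME/SE/BE models. Subjects missing any core
#' feature are dropped with a message.
#'
#' @param roi_means long `data.frame` stacking [extract_roi_means()] outputs
#'   with an added `subject` column.
#' @param covariates `data.frame` with columns `subject`, `group` (0 = HS,
#'   1 = OA), `age`, and optionally `sex`, `bmi`.
#' @param model `"me"`, `"be"` or `"se"`.
#' @param scope `"multi"` or `"global"`.
#' @return `data.frame`: covariates then feature columns; attribute
#'   `"features"` holds the feature column names.
#' @export
build_feature_table <- function(roi_means, covariates, model,
                                scope = c("multi", "global")) {
  scope <- match.arg(scope)
  model <- model_id(model)
  pnames <- model_param_names(model)
  rois <- if (scope == "multi") names(roi_legend()) else "Global"
  stopifnot(all(c("subject", "roi", pnames) %in% names(roi_means)),
            all(c("subject", "group", "age") %in% names(covariates)))
  subjects <- covariates$subject
  feat_names <- as.vector(t(outer(pnames, rois, paste, sep = "_")))
  X <- matrix(NA_real_, length(subjects), length(feat_names),
              dimnames = list(NULL, feat_names))
  for (i in seq_along(subjects)) {
    rows <- roi_means[roi_means$subject == subjects[i], , drop = FALSE]
    for (p in pnames) for (r in rois) {
      v <- rows[[p]][rows$roi == r]
      if (length(v) == 1L) X[i, paste(p, r, sep = "_")] <- v
    }
  }
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sprintf("dropping %d subject(s) with missing ROI features: %s",
                    sum(!keep), paste(subjects[!keep], collapse = ", ")))
  }
  out <- cbind(covariates[keep, , drop = FALSE],
               as.data.frame(X[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "features") <- feat_names
  out
}

#' Feature column names of a feature table
#' @param ft a table from [build_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(ft) attr(ft, "features")

#' Group-wise median/IQR summaries of features
#'
#' Reporting-style summary: per feature, median and interquartile range in
#' each group.
#'
#' @param ft a feature table.
#' @param group optional 0/1 vector (defaults to `ft$group`).
#' @return `data.frame` with one row per feature.
#' @export
summarize_features <- function(ft, group = ft$group) {
  feats <- feature_columns(ft)
  do.call(rbind, lapply(feats, function(f) {
    x0 <- ft[[f]][group == 0]; x1 <- ft[[f]][group == 1]
    q0 <- stats::quantile(x0, c(0.25, 0.5, 0.75), names = FALSE)
    q1 <- stats::quantile(x1, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(feature = f,
               median_hs = q0[2], iqr_lo_hs = q0[1], iqr_hi_hs = q0[3],
               median_oa = q1[2], iqr_lo_oa = q1[1], iqr_hi_oa = q1[3])
  }))
}
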