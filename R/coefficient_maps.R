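#' Back-project model slopes into a voxel coefficient map
#'
#' Multiplies each component's voxel-weight map by that component's slope
#' in a fitted prediction model and sums the results into one signed 3D
#' image. The map shows the magnitude and direction of each voxel's
#' contribution to the prediction: with nonnegative loads and weights, a
#' negative slope at a high-weight voxel means more signal there lowers the
#' predicted outcome (probability or severity). Age and intercept terms are
#' excluded — only component slopes are spatial.
#'
#' By default the slopes on the standardized-predictor scale are used, so
#' component contributions are comparable in magnitude; set
#' `slope_scale = "original"` for raw slopes.
#'
#' @param model a `prediction_model` from [fit_elastic_net()].
#' @param D r x voxels dictionary (an `nmf_model` is also accepted).
#' @param grid the [masked_grid()] of the dictionary columns.
#' @param components optional character vector naming which model
#'   predictors correspond to the rows of `D`, in order; defaults to all
#'   predictors except `age`.
#' @param slope_scale `"standardized"` (default) or `"original"`.
#' @return object of class `coefficient_map`: `volume` (3D array, zero off
#'   mask), `flat` (masked vector), `grid`, `outcome`, `slopes` used.
#' @export
build_coefficient_map <- function(model, D, grid,
                                  components = NULL,
                                  slope_scale = c("standardized", "original")) {
  slope_scale <- match.arg(slope_scale)
  if (inherits(D, "nmf_model")) {
    if (missing(grid) || is.null(grid)) grid <- D$grid
    D <- D$dictionary
  }
  if (is.null(grid)) stop("a masked_grid is required")
  slopes_all <- if (slope_scale == "standardized") model$coefficients_std
                else model$coefficients
  if (is.null(components))
    components <- setdiff(model$predictors, "age")
  missing_comp <- setdiff(components, model$predictors)
  if (length(missing_comp))
    stop("predictors not in model: ", paste(missing_comp, collapse = ", "))
  slopes <- slopes_all[components]
  if (length(slopes) != nrow(D))
    stop("slope count (", length(slopes), ") does not match dictionary rows (",
         nrow(D), ")")
  if (ncol(D) != n_voxels(grid))
    stop("dictionary columns do not match grid mask size")
  flat <- as.numeric(crossprod(D, slopes))   # sum_j slope_j * D[j, ]
  structure(list(volume = devectorize_volume(flat, grid, fill = 0),
                 flat = flat, grid = grid, outcome = model$outcome,
                 slopes = slopes, slope_scale = slope_scale),
            class = "coefficient_map")
}

#' @export
print.coefficient_map <- function(x, ...) {
  cat("coefficient map for '", x$outcome, "' (", x$slope_scale,
      " slopes): range [", signif(min(x$flat), 3), ", ",
      signif(max(x$flat), 3), "]\n", sep = "")
  invisible(x)
}

#' Write a coefficient map or dictionary to NIfTI
#'
#' The dictionary is written as a 4D image (one 3D component map per
#' volume); a coefficient map as a signed 3D image. Both use the grid's
#' affine.
#'
#' @param x a `coefficient_map` or `nmf_model`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_map_nifti <- function(x, path) {
  if (inherits(x, "coefficient_map")) {
    write_nifti(x$volume, path, affine = x$grid$affine)
  } else if (inherits(x, "nmf_model")) {
    if (is.null(x$grid)) stop("nmf_model carries no grid; cannot devectorize")
    r <- nrow(x$dictionary)
    arr <- array(0, dim = c(x$grid$shape, r))
    for (j in seq_len(r))
      arr[, , , j] <- devectorize_volume(x$dictionary[j, ], x$grid, 0)
    write_nifti(arr, path, affine = x$grid$affine)
  } else stop("unsupported object")
  invisible(path)
}
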