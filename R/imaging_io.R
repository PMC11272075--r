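#' Masked sampling grid
#'
#' A `masked_grid` fixes, once per study, the mapping between 3D voxel space
#' and the flat voxel vectors consumed by the factorization. The flat index
#' runs over mask voxels in column-major (first-axis-fastest) order, i.e. the
#' order in which R stores arrays, so `vectorize_volume()` /
#' `devectorize_volume()` are cheap and byte-reproducible across platforms.
#'
#' @param mask logical (or 0/1 numeric) 3D array selecting the voxels kept.
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @return object of class `masked_grid` with fields `shape`, `affine`,
#'   `mask` (logical array) and `voxel_index` (integer matrix, one row per
#'   mask voxel, columns i/j/k).
#' @export
masked_grid <- function(mask, affine = diag(4)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stop("affine must be a 4x4 matrix")
  m <- array(as.logical(mask != 0), dim = dim(mask))
  if (anyNA(m)) stop("mask contains NA")
  idx <- which(m)                      # column-major order, axis 1 fastest
  if (length(idx) == 0L) stop("mask selects no voxels")
  structure(
    list(shape = dim(m), affine = affine, mask = m,
         voxel_index = arrayInd(idx, dim(m)), flat_index = idx),
    class = "masked_grid")
}

#' @export
print.masked_grid <- function(x, ...) {
  cat("masked_grid:", paste(x$shape, collapse = " x "),
      "grid,", nrow(x$voxel_index), "mask voxels\n")
  invisible(x)
}

n_voxels <- function(grid) length(grid$flat_index)

#' Convert between 3D volumes and flat masked vectors
#'
#' `vectorize_volume()` extracts the masked voxels of a volume in the grid's
#' declared order; `devectorize_volume()` writes them back, filling voxels
#' outside the mask with `fill`. The two are exact inverses on the mask.
#'
#' @param volume numeric 3D array with `dim(volume) == grid$shape`.
#' @param grid a [masked_grid()].
#' @param x numeric vector of length `nrow(grid$voxel_index)`.
#' @param fill value placed outside the mask (default 0).
#' @export
vectorize_volume <- function(volume, grid) {
  if (inherits(volume, "nifti_volume")) volume <- volume$data
  if (!identical(as.integer(dim(volume)), as.integer(grid$shape)))
    stop("volume shape ", paste(dim(volume), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  as.double(volume[grid$flat_index])
}

#' @rdname vectorize_volume
#' @export
devectorize_volume <- function(x, grid, fill = 0) {
  if (length(x) != n_voxels(grid))
    stop("vector length ", length(x), " does not match mask size ",
         n_voxels(grid))
  out <- array(as.double(fill), dim = grid$shape)
  out[grid$flat_index] <- x
  out
}

#' Subject-by-voxel matrix
#'
#' Container for the nonnegative matrix the factorization consumes: one row
#' per subject, one column per mask voxel (in `grid` order), plus the
#' metadata needed to map columns back to 3D space.
#'
#' @param values numeric matrix, subjects x voxels, all entries >= 0.
#' @param subject_ids character vector of unique IDs, one per row.
#' @param modality one of `"MRI"`, `"FDG"`, `"other"`.
#' @param grid the [masked_grid()] the columns refer to.
#' @export
voxel_matrix <- function(values, subject_ids, modality = c("MRI", "FDG", "other"),
                         grid) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (nrow(values) != length(subject_ids))
    stop("row count must equal number of subject IDs")
  if (anyDuplicated(subject_ids)) stop("subject IDs must be unique")
  if (ncol(values) != n_voxels(grid))
    stop("column count ", ncol(values), " does not match mask size ",
         n_voxels(grid))
  if (!all(is.finite(values))) stop("voxel matrix contains non-finite values")
  if (min(values) < 0) stop("voxel matrix contains negative values")
  rownames(values) <- subject_ids
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 modality = modality, grid = grid),
            class = "voxel_matrix")
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat("voxel_matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "voxels (", x$modality, ")\n")
  invisible(x)
}

#' Load a set of NIfTI images into a subject-by-voxel matrix
#'
#' All images must share the grid's shape and (within `1e-4` entrywise)
#' affine. Masked values must be finite; values in `[-1e-6, 0)` are treated
#' as interpolation noise and clamped to zero, anything more negative is an
#' error because the factorization requires nonnegative input.
#'
#' @param paths character vector of NIfTI file paths, one per subject.
#' @param grid a [masked_grid()].
#' @param modality modality label stored with the matrix.
#' @param subject_ids optional IDs; defaults to file basenames without
#'   extension.
#' @return a [voxel_matrix()] whose row `i` holds the masked voxels of
#'   `paths[i]`.
#' @export
load_image_set <- function(paths, grid, modality = c("MRI", "FDG", "other"),
                           subject_ids = NULL) {
  modality <- match.arg(modality)
  if (length(paths) == 0L) stop("no image paths given")
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  values <- matrix(0, nrow = length(paths), ncol = n_voxels(grid))
  for (i in seq_along(paths)) {
    img <- read_nifti(paths[i])
    if (!identical(as.integer(dim(img$data)), as.integer(grid$shape)))
      stop("image shape mismatch in ", paths[i], ": got ",
           paste(dim(img$data), collapse = "x"), ", expected ",
           paste(grid$shape, collapse = "x"))
    if (max(abs(img$affine - grid$affine)) > 1e-4)
      stop("affine mismatch in ", paths[i])
    v <- vectorize_volume(img$data, grid)
    if (!all(is.finite(v)))
      stop("non-finite voxel values inside mask in ", paths[i])
    if (min(v) < -1e-6)
      stop("negative voxel values inside mask in ", paths[i],
           " (min = ", signif(min(v), 4), ")")
    values[i, ] <- pmax(v, 0)
  }
  voxel_matrix(values, subject_ids, modality, grid)
}

#' SUVR normalization of a PET volume
#'
#' Divides every voxel by the median uptake within a reference region
#' (conventionally the eroded supratentorial white matter), yielding a
#' standardized uptake value ratio image whose reference-region median is 1.
#' Erosion of the reference mask is the caller's responsibility.
#'
#' @param pet numeric 3D array (or `nifti_volume`) of PET uptake.
#' @param reference_mask logical/0-1 3D array selecting reference voxels.
#' @return 3D array of SUVR values, same shape as `pet`.
#' @export
suvr_normalize <- function(pet, reference_mask) {
  if (inherits(pet, "nifti_volume")) pet <- pet$data
  ref <- as.logical(reference_mask != 0)
  if (!identical(dim(pet), dim(reference_mask)))
    stop("pet and reference_mask shapes differ")
  if (!any(ref)) stop("reference mask selects no voxels")
  med <- stats::median(pet[ref])
  if (!is.finite(med) || med <= 0)
    stop("reference-region median is not positive (", med,
         "); cannot form SUVR")
  pet / med
}
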