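#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`).
#' Only the subset of the format that this package produces and consumes is
#' supported: 3D/4D images, datatypes uint8/int16/int32/float32/float64,
#' the sform affine, and the global slope/intercept scaling. This is not a
#' general-purpose NIfTI library; it exists because the package must be
#' usable without any external imaging dependency.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti`: a list of class `nifti_volume` with elements
#'   `data` (numeric array), `affine` (4x4 voxel-to-world matrix) and
#'   `pixdim` (voxel sizes).
#' @name nifti_io
NULL

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))

  # header offsets follow the NIfTI-1 standard (348-byte header)
  hdr0 <- readBin(con, "raw", 4)
  if (readBin(hdr0, "integer", 1, size = 4, endian = "little") == 348L) {
    endian <- "little"
  } else if (readBin(hdr0, "integer", 1, size = 4, endian = "big") == 348L) {
    endian <- "big"
  } else {
    stop("not a NIfTI-1 file (bad header size): ", path)
  }
  readBin(con, "raw", 36)                                   # bytes 4..39
  dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent fields
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)     # bitpix
  readBin(con, "integer", 1, size = 2, endian = endian)     # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)                                  # bytes 120..251
  readBin(con, "integer", 1, size = 2, endian = endian)     # qform_code
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "double", 6, size = 4, endian = endian)      # quatern+qoffset
  srow <- matrix(readBin(con, "double", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                                   # intent_name
  magic <- readBin(con, "raw", 4)
  if (rawToChar(magic[1:3]) != "n+1")
    stop("unsupported NIfTI magic in ", path, " (two-file .hdr/.img?)")

  ndim <- dim[1]
  if (ndim < 3 || ndim > 4) stop("only 3D/4D NIfTI supported, got ndim=", ndim)
  dims <- dim[2:(1 + ndim)]
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)

  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, spec$what, n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(as.double(data), dim = dims)

  affine <- diag(4)
  if (sform_code > 0) affine[1:3, ] <- srow
  structure(list(data = arr, affine = affine, pixdim = pixdim[2:4]),
            class = "nifti_volume")
}

#' @rdname nifti_io
#' @param data numeric 3D or 4D array (a `nifti_volume` is also accepted).
#' @param affine 4x4 voxel-to-world matrix written as the sform.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @export
write_nifti <- function(data, path, affine = diag(4),
                        datatype = c("float32", "float64")) {
  if (inherits(data, "nifti_volume")) {
    if (missing(affine)) affine <- data$affine
    data <- data$data
  }
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("write_nifti expects a 3D or 4D array")
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stop("affine must be a 4x4 matrix")
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  dimfield <- c(length(dims), dims, rep(1L, 7 - length(dims)))

  w_i32(348L)                          # sizeof_hdr           [0]
  w_raw(36)                            # data_type..dim_info  [4]
  w_i16(dimfield)                      # dim[8]               [40]
  w_raw(14)                            # intent_p*, code      [56]
  w_i16(code); w_i16(8L * size)        # datatype, bitpix     [70]
  w_i16(0L)                            # slice_start          [74]
  w_f32(c(1, pix, rep(1, 4)))          # pixdim[8], qfac=1    [76]
  w_f32(352); w_f32(1); w_f32(0)       # vox_offset,slope,int [108]
  w_raw(4)                             # slice_end/code/units [120]
  w_f32(c(0, 0, 0, 0))                 # cal_max..toffset     [124]
  w_i32(c(0L, 0L))                     # glmax, glmin         [140]
  w_raw(80); w_raw(24)                 # descrip, aux_file    [148]
  w_i16(0L); w_i16(2L)                 # qform=0, sform=2     [252]
  w_f32(rep(0, 6))                     # quatern, qoffset     [256]
  w_f32(t(affine[1:3, ]))              # srow_x/y/z           [280]
  w_raw(16)                            # intent_name          [328]
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic         [344]
  w_raw(4)                             # extension flag       [348]
  writeBin(as.double(data), con, size = size, endian = "little")
  invisible(path)
}
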