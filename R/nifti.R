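# --- minimal NIfTI-1 I/O ---------------------------------------------------
#
# Self-contained single-file NIfTI-1 (.nii / .nii.gz) support, sufficient for
# this package's volumes: 3D/4D arrays, datatypes uint8 / int16 / int32 /
# float32 / float64, voxel spacing via pixdim, scl_slope/scl_inter honored on
# read. Orientation (qform/sform) is not interpreted: volumes are treated in
# raw voxel index space, which is adequate for a pipeline whose images and
# labels share one grid.

nifti_datatypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, size = 4L, what = "numeric", signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, size = 8L, what = "numeric", signed = TRUE))

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param x 3D or 4D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Voxel size in mm along the spatial axes (length 3).
#' @param datatype Storage type: `"float32"` (default) or `"uint8"` (for
#'   label masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  dt <- nifti_datatypes[[datatype]]
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("`x` must be a 3D or 4D array")
  if (datatype == "uint8" && any(x < 0 | x > 255))
    stop("uint8 storage requires values in [0, 255]")
  dim8 <- integer(8)
  dim8[1] <- length(d)
  dim8[2:(1 + length(d))] <- d
  dim8[dim8 == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- spacing
  pixdim[5:8] <- 1

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                       # sizeof_hdr
  wraw(36L)                          # data_type .. dim_info (unused)
  wb(as.integer(dim8), 2L)           # dim[8]
  wb(numeric(3), 4L)                 # intent_p1..p3
  wb(0L, 2L)                         # intent_code
  wb(dt$code, 2L)                    # datatype
  wb(dt$bitpix, 2L)                  # bitpix
  wb(0L, 2L)                         # slice_start
  wb(pixdim, 4L)                     # pixdim[8]
  wb(352, 4L)                        # vox_offset
  wb(c(1, 0), 4L)                    # scl_slope, scl_inter
  wb(0L, 2L); wraw(2L)               # slice_end, slice_code, xyzt_units
  wb(numeric(4), 4L)                 # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                  # glmax, glmin
  wraw(104L)                         # descrip + aux_file
  wb(c(0L, 0L), 2L)                  # qform_code, sform_code
  wb(numeric(6), 4L)                 # quatern + qoffset
  wb(c(spacing[1], 0, 0, 0,  0, spacing[2], 0, 0,  0, 0, spacing[3], 0), 4L)
  wraw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  wraw(4L)                           # extension flag
  v <- as.vector(x)
  if (dt$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return Numeric array with attribute `spacing` (voxel size, mm).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rb <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rb(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rb(0L, "integer", 1L, 4L, endian = "big") != 348L)
      stop(path, " is not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(path, " is not a NIfTI-1 file (bad magic '", magic, "')")
  dim8 <- rb(40L, "integer", 8L, 2L, endian = endian)
  ndim <- dim8[1]
  if (ndim < 1L || ndim > 7L) stop("unsupported dim[0] = ", ndim)
  dims <- dim8[2:(1 + ndim)]
  code <- rb(70L, "integer", 1L, 2L, endian = endian)
  dt <- Filter(function(z) z$code == code, nifti_datatypes)
  if (length(dt) == 0L) stop("unsupported NIfTI datatype code ", code)
  dt <- dt[[1]]
  pixdim <- rb(76L, "numeric", 8L, 4L, endian = endian)
  vox_offset <- rb(108L, "numeric", 1L, 4L, endian = endian)
  scl_slope <- rb(112L, "numeric", 1L, 4L, endian = endian)
  scl_inter <- rb(116L, "numeric", 1L, 4L, endian = endian)
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  if (length(v) < n) stop("truncated NIfTI data in ", path)
  v <- as.numeric(v)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  out <- array(v, dim = dims)
  attr(out, "spacing") <- pixdim[2:4]
  out
}
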