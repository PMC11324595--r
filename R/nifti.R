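# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format this pipeline needs is supported:
# uncompressed or gzipped single-file volumes, datatypes uint8 / int16 /
# int32 / float32 / float64, little- or big-endian, sform or pixdim
# geometry. No extensions, no .hdr/.img pairs, no qform quaternion
# decoding (qform-only files fall back to pixdim spacing).

.NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array with its voxel-to-world affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array with the header's
#'   spatial/temporal dimensions), `affine` (4x4 voxel-to-world matrix,
#'   0-based voxel indices), and `pixdim` (voxel spacings).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd <- function(offset, what, n, size) {
    readBin(hdr_raw[(offset + 1L):(offset + n * size)], what,
            n = n, size = size, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic in ", path)
  dim       <- rd(40L, "integer", 8L, 2L)
  datatype  <- rd(70L, "integer", 1L, 2L)
  pixdim    <- rd(76L, "double", 8L, 4L)
  vox_offset<- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code<- rd(254L, "integer", 1L, 2L)
  srow      <- rbind(rd(280L, "double", 4L, 4L),
                     rd(296L, "double", 4L, 4L),
                     rd(312L, "double", 4L, 4L))

  ndim <- dim[1L]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in ", path)
  shape <- dim[2L:(1L + ndim)]
  shape[shape == 0L] <- 1L
  n_vals <- prod(shape)

  spec <- Filter(function(d) d$code == datatype, .NIFTI_DTYPES)
  if (length(spec) == 0L) stop("unsupported NIfTI datatype code ", datatype)
  spec <- spec[[1L]]

  # skip from end of header to vox_offset (gz streams cannot seek)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n_vals, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n_vals) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  list(data = data, affine = affine, pixdim = pixdim[2:(1 + min(ndim, 3L))])
}

#' Write a NIfTI-1 volume
#'
#' Writes an array (3D or 4D) as a single-file NIfTI-1 image. The affine is
#' stored in the sform (code 1); gzip compression is chosen from the file
#' extension.
#'
#' @param data Numeric array, 1 to 4 dimensions.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param datatype One of `"float32"`, `"float64"`, `"int32"`, `"int16"`,
#'   `"uint8"`. Integer types are range-checked before truncation.
#' @param tr Repetition time written into `pixdim[4]` (seconds); used for
#'   4D series.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32",
                        tr = 1) {
  if (!is.array(data)) data <- as.array(data)
  shape <- dim(data)
  if (length(shape) > 7L) stop("too many dimensions for NIfTI")
  spec <- .NIFTI_DTYPES[[match.arg(datatype, names(.NIFTI_DTYPES))]]
  if (spec$what == "integer") {
    if (any(data != round(data))) stop("non-integer data for integer datatype")
    lim <- if (spec$code == 2L) c(0, 255) else
           if (spec$code == 4L) c(-32768, 32767) else c(-2^31, 2^31 - 1)
    if (any(data < lim[1] | data > lim[2])) stop("data out of range for ", datatype)
  }
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")

  dim_field <- rep(1L, 8L)
  dim_field[1L] <- length(shape)
  dim_field[2L:(1L + length(shape))] <- as.integer(shape)
  pixdim <- rep(0, 8L)
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim[5] <- tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                  # sizeof_hdr
  w_raw(35L)                                   # data_type..regular
  writeBin(as.raw(0L), con)                    # dim_info
  w_i16(dim_field)                             # dim
  w_f32(c(0, 0, 0)); w_i16(0L)                 # intent_p*, intent_code
  w_i16(spec$code); w_i16(spec$bitpix); w_i16(0L)
  w_f32(pixdim)
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                         # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0L, 0L))                             # glmax, glmin
  descrip <- charToRaw("bwasr")
  w_raw(0L); writeBin(c(descrip, raw(80L - length(descrip))), con)  # descrip
  w_raw(24L)                                   # aux_file
  w_i16(0L); w_i16(1L)                         # qform_code=0, sform_code=1
  w_f32(c(0, 0, 0, 0, 0, 0))                   # quatern/qoffset
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                                    # extension flag
  if (spec$what == "integer") {
    writeBin(as.integer(data), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = spec$size, endian = "little")
  }
  invisible(path)
}
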