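# Minimal NIfTI-1 single-file (.nii / .nii.gz) support.
#
# Only the single-file variant (magic "n+1") is handled. Data types covered:
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64). Byte order is
# detected from sizeof_hdr. scl_slope/scl_inter are applied on read. All
# computation in the package is double precision; maps are written as float32
# (see write_nifti).

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  # gzfile transparently reads uncompressed files too
  gzfile(path, open)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an R array,
#' together with the voxel grid geometry. The affine is taken from the sform
#' when `sform_code > 0`, else from the qform quaternion, else from `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array, 3D or 4D), `dim`
#'   (integer dimensions), `voxel_size` (first three `pixdim` entries, mm),
#'   `affine` (4x4 voxel-to-world matrix, 0-based voxel indices), `tr_seconds`
#'   (`pixdim[4]`, or `NA` for 3D images) and `header` (raw header fields).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 2L * n)],
                                     "integer", n = n, size = 2L, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 4L * n)],
                                     "integer", n = n, size = 4L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1L):(off + 4L * n)],
                                     "double", n = n, size = 4L, endian = endian)

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L) stop("only 3D/4D images supported, got ndim=", ndim)
  dims <- pmax(dim_field[2:(1 + ndim)], 1L)

  datatype <- rd_i16(70L, 1L)
  type <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(type)) stop("unsupported NIfTI datatype code ", datatype, " in ", path)

  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  quatern <- rd_f32(256L, 3L)
  qoffset <- rd_f32(268L, 3L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_affine(quatern, qoffset, pixdim)
  } else {
    diag(c(pixdim[2:4], 1))
  }

  # gz connections cannot seek: consume bytes between header and data
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)

  n_vox <- prod(dims)
  data <- readBin(con, type$what, n = n_vox, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(data) < n_vox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  data <- array(as.double(data), dim = dims)

  list(
    data = data,
    dim = as.integer(dims),
    voxel_size = abs(pixdim[2:4]),
    affine = affine,
    tr_seconds = if (ndim == 4L) pixdim[5] else NA_real_,
    header = list(datatype = datatype, sform_code = sform_code,
                  qform_code = qform_code, endian = endian,
                  descrip = rawToChar(hdr_raw[149:228][hdr_raw[149:228] != as.raw(0)]))
  )
}

# qform: quaternion (b,c,d) -> rotation, with qfac = pixdim[1] (0 treated as 1)
qform_affine <- function(quatern, qoffset, pixdim) {
  b <- quatern[1]; c <- quatern[2]; d <- quatern[3]
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - c * c - b * b
  ), nrow = 3, byrow = TRUE)
  qfac <- if (pixdim[1] == 0) 1 else pixdim[1]
  S <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(S, qoffset), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D numeric array as a single-file NIfTI-1 image. Data are
#' stored as float32 by default (float64 available); the affine is recorded in
#' the sform (code 2) and mirrored in pixdim. Output is gzip-compressed when
#' the path ends in `.gz`.
#'
#' @param data Numeric array, 3D or 4D.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @param tr_seconds Repetition time written to `pixdim[4]` (4D only).
#' @param datatype `"float32"` or `"float64"`.
#' @param descrip Short free-text header description (<= 79 bytes).
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, affine = NULL, voxel_size = c(1, 1, 1),
                        tr_seconds = 0, datatype = c("float32", "float64"),
                        descrip = "") {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L))) {
    stop("data must be a 3D or 4D array")
  }
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr_pad <- function(s, n) {
    r <- charToRaw(as.character(s))
    if (length(r) > n) r <- r[seq_len(n)]
    writeBin(c(r, raw(n - length(r))), con)
  }

  wr_i32(348L)                                   # sizeof_hdr
  wr_pad("", 10L); wr_pad("", 18L)               # data_type, db_name
  wr_i32(0L); wr_i16(0L); wr_pad("r", 1L)        # extents, session_error, regular
  writeBin(raw(1L), con)                         # dim_info
  dim_field <- integer(8L); dim_field[1] <- length(dims)
  dim_field[2:(1 + length(dims))] <- dims
  dim_field[dim_field == 0L] <- 1L
  wr_i16(dim_field)
  wr_f32(c(0, 0, 0)); wr_i16(0L)                 # intent_p1..p3, intent_code
  wr_i16(code); wr_i16(8L * size); wr_i16(0L)    # datatype, bitpix, slice_start
  pixdim <- c(1, voxel_size, tr_seconds, 0, 0, 0)
  wr_f32(pixdim)
  wr_f32(352); wr_f32(1); wr_f32(0)              # vox_offset, scl_slope, scl_inter
  wr_i16(0L); writeBin(raw(1L), con)             # slice_end, slice_code
  writeBin(as.raw(10L), con)                     # xyzt_units: mm | sec
  wr_f32(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wr_i32(c(0L, 0L))                              # glmax, glmin
  wr_pad(descrip, 80L); wr_pad("", 24L)          # descrip, aux_file
  wr_i16(0L); wr_i16(2L)                         # qform_code, sform_code
  wr_f32(c(0, 0, 0)); wr_f32(c(0, 0, 0))         # quatern, qoffset
  wr_f32(affine[1, ]); wr_f32(affine[2, ]); wr_f32(affine[3, ])
  wr_pad("", 16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  writeBin(raw(4L), con)                         # extension flag
  writeBin(as.double(data), con, size = size, endian = "little")
  invisible(path)
}
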