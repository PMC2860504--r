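# Mask geometry and masked time series.
#
# Voxel ordering convention: in-mask voxels are numbered 1..n in ascending
# linear index of the 3D grid with the first axis fastest (R's native array
# order). This ordering is stable and shared by every module.

#' Construct a mask geometry
#'
#' Binds a binary 3D mask to its grid geometry and fixes the bijection between
#' in-mask grid coordinates and row indices `1..n` used throughout the
#' package.
#'
#' @param inside Logical 3D array; `TRUE` marks in-mask voxels.
#' @param voxel_size Numeric length-3 voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices);
#'   defaults to a scaling by `voxel_size`.
#' @return An object of class `mask_geometry` with fields `shape`,
#'   `voxel_size`, `affine`, `inside`, `mask_linear` (linear indices of
#'   in-mask voxels, ascending) and `n`.
#' @export
mask_geometry <- function(inside, voxel_size = c(1, 1, 1), affine = NULL) {
  stopifnot(is.logical(inside), length(dim(inside)) == 3L)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  mask_linear <- which(inside)
  if (length(mask_linear) == 0L) stop("mask is empty")
  structure(
    list(shape = dim(inside), voxel_size = as.double(voxel_size),
         affine = affine, inside = inside,
         mask_linear = mask_linear, n = length(mask_linear)),
    class = "mask_geometry"
  )
}

#' @export
print.mask_geometry <- function(x, ...) {
  cat(sprintf("mask_geometry: grid %s, voxel %s mm, %d in-mask voxels\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"), x$n))
  invisible(x)
}

#' Grid coordinates of in-mask voxels
#'
#' @param geometry A [mask_geometry()].
#' @return Integer `n x 3` matrix of 1-based grid coordinates, row `i` being
#'   the coordinate of in-mask voxel `i`.
#' @export
mask_coordinates <- function(geometry) {
  arrayInd(geometry$mask_linear, geometry$shape)
}

#' Map an in-mask value vector onto the 3D grid
#'
#' @param values Numeric vector of length `geometry$n`.
#' @param geometry A [mask_geometry()].
#' @param background Fill value outside the mask.
#' @return A 3D numeric array on the mask's grid.
#' @export
unmask <- function(values, geometry, background = 0) {
  if (length(values) != geometry$n) {
    stop("length(values) = ", length(values), " but mask has n = ", geometry$n)
  }
  arr <- array(background, dim = geometry$shape)
  arr[geometry$mask_linear] <- values
  arr
}

#' Construct a masked time-series object
#'
#' @param data Numeric `n x T` matrix, one row per in-mask voxel in mask
#'   order.
#' @param geometry A [mask_geometry()] with `n` equal to `nrow(data)`.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @return An object of class `masked_series`.
#' @export
masked_series <- function(data, geometry, tr_seconds) {
  stopifnot(is.matrix(data), nrow(data) == geometry$n)
  if (!is.finite(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (ncol(data) < 8L) stop("time series too short: T = ", ncol(data), " < 8")
  if (!all(is.finite(data))) stop("non-finite values in series data")
  structure(list(data = data, geometry = geometry,
                 tr_seconds = as.double(tr_seconds)),
            class = "masked_series")
}

#' @export
print.masked_series <- function(x, ...) {
  cat(sprintf("masked_series: n = %d voxels, T = %d volumes, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Load a masked 4D series from NIfTI files
#'
#' Reads a 4D BOLD-like image and a 3D binary mask on the same grid and
#' returns the in-mask voxel-by-time matrix. Voxels whose series is constant
#' or contains non-finite values are removed from the mask (correlation is
#' undefined for them); the number removed is reported with a warning.
#'
#' @param bold_path Path to the 4D NIfTI image.
#' @param mask_path Path to the 3D NIfTI mask (nonzero = inside).
#' @param tr_seconds Repetition time override; defaults to the BOLD header's
#'   `pixdim[4]` when positive.
#' @param affine_tol Maximum absolute per-entry difference allowed between the
#'   two affines.
#' @return A [masked_series()].
#' @export
load_series <- function(bold_path, mask_path, tr_seconds = NULL,
                        affine_tol = 1e-4) {
  bold <- read_nifti(bold_path)
  mask <- read_nifti(mask_path)
  if (length(bold$dim) != 4L) stop("expected 4D image, got ", length(bold$dim), "D")
  if (length(mask$dim) != 3L) stop("expected 3D mask, got ", length(mask$dim), "D")
  if (!identical(bold$dim[1:3], mask$dim)) {
    stop(sprintf("grid mismatch: bold %s vs mask %s",
                 paste(bold$dim[1:3], collapse = "x"),
                 paste(mask$dim, collapse = "x")))
  }
  if (max(abs(bold$affine - mask$affine)) > affine_tol) {
    stop("affine mismatch between bold and mask beyond tolerance ", affine_tol)
  }
  inside <- mask$data != 0
  if (!any(inside)) stop("mask is empty")
  if (is.null(tr_seconds)) {
    tr_seconds <- if (is.finite(bold$tr_seconds) && bold$tr_seconds > 0)
      bold$tr_seconds else stop("TR not present in header; pass tr_seconds")
  }

  n_t <- bold$dim[4]
  flat <- matrix(bold$data, nrow = prod(bold$dim[1:3]), ncol = n_t)
  data <- flat[which(inside), , drop = FALSE]

  ok <- apply(data, 1L, function(r) all(is.finite(r))) &
    (apply(data, 1L, stats::var) > 0)
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance or non-finite voxel(s) removed from mask")
    inside[which(inside)[!ok]] <- FALSE
    data <- data[ok, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("mask is empty after filtering degenerate voxels")

  geom <- mask_geometry(inside, voxel_size = mask$voxel_size,
                        affine = mask$affine)
  masked_series(data, geom, tr_seconds)
}

#' Save an in-mask value vector as a 3D NIfTI map
#'
#' Values are placed on the grid by the mask bijection; voxels outside the
#' mask are written as zero and flagged in the header description. Storage is
#' float32: centrality values are entries of a unit-norm vector, for which
#' single precision is ample, while all computation stays double.
#'
#' @param values Numeric vector of length `geometry$n`.
#' @param geometry A [mask_geometry()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype On-disk scalar type, default float32.
#' @return Invisibly, `path`.
#' @export
save_map <- function(values, geometry, path, datatype = "float32") {
  arr <- unmask(values, geometry)
  write_nifti(arr, path, affine = geometry$affine,
              voxel_size = geometry$voxel_size, datatype = datatype,
              descrip = "ecmap map; background=0 outside mask")
}
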