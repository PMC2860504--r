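# Voxel-pair similarity in the time domain.
#
# The similarity matrix A is symmetric and non-negative so that its dominant
# eigenvector is unique and entrywise non-negative (Perron-Frobenius). Scaled
# correlation admits an exact factored form
#   A = (Z Z^T + 1 1^T) / 2,  Z[i, ] = (x_i - mean) / (sd * sqrt(T)),
# (population sd, so Z Z^T is exactly the correlation matrix) which lets
# matrix-vector products run in O(nT) without materializing the n x n matrix.

#' Pearson correlation of two series
#'
#' Sample linear correlation; symmetric, `pearson(x, x) = 1`. Either sd
#' convention (population or sample) gives the same value because the factor
#' cancels.
#'
#' @param x,y Numeric vectors of equal length with positive variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance series: correlation undefined")
  }
  stats::cor(x, y)
}

#' Re-scale a correlation to a non-negative similarity
#'
#' The affine map `r -> (r + 1) / 2`, the unique increasing affine map
#' sending `[-1, 1]` onto `[0, 1]`. Strong anti-correlation maps near 0,
#' independence to 0.5.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param tol Tolerance for out-of-range input.
#' @return Value(s) in `[0, 1]`.
#' @export
scale_correlation <- function(r, tol = 1e-8) {
  if (any(abs(r) > 1 + tol)) stop("|r| > 1: not a correlation")
  pmin(pmax((r + 1) / 2, 0), 1)
}

#' Absolute-value handling of negative correlations
#'
#' Alternative to [scale_correlation()]: treats strong inverse coupling as
#' strong similarity.
#'
#' @inheritParams scale_correlation
#' @return `|r|`, in `[0, 1]`.
#' @export
abs_correlation <- function(r, tol = 1e-8) {
  if (any(abs(r) > 1 + tol)) stop("|r| > 1: not a correlation")
  pmin(abs(r), 1)
}

#' Construct a similarity matrix object
#'
#' @param n Node count.
#' @param form `"dense"` or `"factored"`.
#' @param dense Symmetric non-negative `n x n` matrix (dense form).
#' @param factor `n x k` matrix `Z` such that `A = (Z Z^T + 1 1^T) / 2`
#'   (factored form; only exact for scaled correlation).
#' @param metric Provenance tag, e.g. `"scaled-corr"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(n, form, dense = NULL, factor = NULL,
                              metric = "unknown") {
  form <- match.arg(form, c("dense", "factored"))
  if (form == "dense") {
    stopifnot(is.matrix(dense), nrow(dense) == n, ncol(dense) == n)
    if (max(abs(dense - t(dense))) > 1e-10) stop("similarity matrix not symmetric")
    if (min(dense) < -1e-12) stop("similarity matrix has negative entries")
    dense[dense < 0] <- 0
  } else {
    stopifnot(is.matrix(factor), nrow(factor) == n)
  }
  structure(list(n = as.integer(n), form = form, dense = dense,
                 factor = factor, metric = metric),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: n = %d, form = %s, metric = %s\n",
              x$n, x$form, x$metric))
  invisible(x)
}

#' Materialize a similarity matrix as dense
#'
#' @param A A [similarity_matrix()].
#' @return The dense `n x n` matrix.
#' @export
as_dense <- function(A) {
  stopifnot(inherits(A, "similarity_matrix"))
  if (A$form == "dense") return(A$dense)
  (tcrossprod(A$factor) + 1) / 2
}

# rows standardized so that tcrossprod(Z) is exactly the correlation matrix
standardize_rows <- function(data) {
  ctr <- data - rowMeans(data)
  ss <- sqrt(rowSums(ctr^2))
  if (any(ss == 0)) stop("zero-variance voxel present; filter the mask first")
  ctr / ss
}

#' Pairwise correlation similarity of a masked series
#'
#' Computes the full voxel-pair similarity matrix under scaled or absolute
#' Pearson correlation. The factored form (scaled mode only) stores the
#' standardized data instead of the `n x n` matrix and supports matrix-free
#' centrality at whole-mask scale.
#'
#' @param series A [masked_series()] (or bare `n x T` matrix).
#' @param mode `"scaled"` (`(r+1)/2`) or `"absolute"` (`|r|`).
#' @param form `"dense"` or `"factored"`; `"factored"` requires
#'   `mode = "scaled"` because `|r|` is not a Gram-plus-rank-one form.
#' @return A [similarity_matrix()] with unit diagonal.
#' @export
correlation_similarity <- function(series, mode = c("scaled", "absolute"),
                                   form = c("dense", "factored")) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  data <- if (inherits(series, "masked_series")) series$data else series
  if (nrow(data) < 2L) stop("need at least 2 voxels")
  if (form == "factored" && mode == "absolute") {
    stop("factored form is only available for mode = 'scaled'")
  }
  z <- standardize_rows(data)
  if (form == "factored") {
    return(similarity_matrix(nrow(data), "factored", factor = z,
                             metric = "scaled-corr"))
  }
  r <- tcrossprod(z)
  r <- pmin(pmax(r, -1), 1)
  a <- if (mode == "scaled") (r + 1) / 2 else abs(r)
  diag(a) <- 1
  a <- (a + t(a)) / 2
  similarity_matrix(nrow(data), "dense", dense = a,
                    metric = if (mode == "scaled") "scaled-corr" else "abs-corr")
}

#' Similarity-matrix product without materialization
#'
#' Applies `A x` for the factored scaled-correlation form
#' `A = (Z Z^T + 1 1^T) / 2` as `(Z (Z^T x) + 1 * sum(x)) / 2`, costing
#' O(nk) per call.
#'
#' @param factor `n x k` factor matrix `Z`.
#' @param x Numeric vector of length `n`.
#' @return Numeric vector `A x` of length `n`.
#' @export
factored_matvec <- function(factor, x) {
  if (length(x) != nrow(factor)) {
    stop("dimension mismatch: factor has ", nrow(factor), " rows, x has length ",
         length(x))
  }
  drop(factor %*% crossprod(factor, x) + sum(x)) / 2
}

# Linear-operator closure for either form.
similarity_operator <- function(A) {
  stopifnot(inherits(A, "similarity_matrix"))
  if (A$form == "dense") {
    dense <- A$dense
    function(x) drop(dense %*% x)
  } else {
    z <- A$factor
    function(x) factored_matvec(z, x)
  }
}

# Irreducibility precondition used before power iteration: every row must
# carry at least one non-zero off-diagonal entry. For the factored scaled
# form all entries are >= 0 with off-diagonals (r+1)/2, zero only at exact
# anti-correlation, so the check materializes nothing.
check_irreducible <- function(A) {
  if (A$form == "dense") {
    d <- A$dense
    diag(d) <- 0
    bad <- which(apply(d, 1L, max) <= 0)
    if (length(bad) > 0L) {
      stop("similarity matrix is reducible: row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " have no non-zero off-diagonal entry; filter the mask")
    }
  } else {
    z <- A$factor
    # row i disconnected iff r_ij = -1 for all j != i: correlation -1 with
    # every other voxel simultaneously is impossible for n > 2 unless all
    # rows are collinear; detect the n = 2 corner exactly.
    if (A$n == 2L && abs(sum(z[1, ] * z[2, ]) + 1) < 1e-12) {
      stop("similarity matrix is reducible: the two voxels are exactly anti-correlated")
    }
  }
  invisible(TRUE)
}
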