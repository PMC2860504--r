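# Group-level statistics for centrality maps: rank-based Gaussianization,
# paired t-maps, and Monte-Carlo cluster-size / cluster-value correction for
# multiple comparisons.

#' Rank-based Gaussianization
#'
#' Maps the empirical distribution of a map onto a normal one: ties receive
#' average ranks, rank `r` maps through the standard normal quantile of
#' `(r - 0.5) / n`, and the result is rescaled to the input's mean and
#' standard deviation. Strictly monotone in the input ranks, hence
#' order-preserving; parametric tests downstream then see approximately
#' Gaussian per-voxel distributions.
#'
#' @param values Numeric vector, `n >= 3`, finite, not all equal.
#' @return Numeric vector of the same length with the input's mean and sd.
#' @export
gaussianize <- function(values) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 values")
  if (!all(is.finite(values))) stop("non-finite values")
  if (max(values) == min(values)) stop("all values equal: no ranking possible")
  r <- rank(values, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / n)
  mean(values) + stats::sd(values) * (z - mean(z)) / stats::sd(z)
}

#' Construct a z-map object
#'
#' Container for a voxel-wise statistic map bound to its mask geometry.
#'
#' @param values Numeric vector of length `geometry$n`.
#' @param geometry A [mask_geometry()].
#' @param df Degrees of freedom of the source test (`NA` for plain z).
#' @return An object of class `zmap`.
#' @export
zmap <- function(values, geometry, df = NA_integer_) {
  stopifnot(length(values) == geometry$n, all(is.finite(values)))
  structure(list(values = values, geometry = geometry, df = df),
            class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat(sprintf("zmap: n = %d, df = %s, range [%.3g, %.3g]\n",
              length(x$values), format(x$df), min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-wise paired t-map
#'
#' Paired t statistic of per-voxel differences `a - b` across matched
#' subjects, `df = subjects - 1`. Voxels whose differences have zero variance
#' are set to 0 and counted in a warning.
#'
#' @param maps_a,maps_b Lists of per-subject `n`-vectors in matched order.
#' @param geometry A [mask_geometry()] shared by all maps.
#' @return A [zmap()] of t statistics.
#' @export
paired_t_map <- function(maps_a, maps_b, geometry) {
  s <- length(maps_a)
  if (length(maps_b) != s) {
    stop("paired design requires equal subject counts: ", s, " vs ", length(maps_b))
  }
  if (s < 2L) stop("need at least 2 subjects")
  a <- do.call(rbind, maps_a)
  b <- do.call(rbind, maps_b)
  if (ncol(a) != geometry$n || ncol(b) != geometry$n) {
    stop("map length does not match mask size n = ", geometry$n)
  }
  d <- a - b
  m <- colMeans(d)
  sdv <- sqrt(colSums((d - rep(m, each = s))^2) / (s - 1))
  tval <- ifelse(sdv > 0, m / (sdv / sqrt(s)), 0)
  n_degenerate <- sum(sdv == 0 & m != 0)
  if (n_degenerate > 0) {
    warning(n_degenerate, " voxel(s) with zero-variance differences set to 0")
  }
  tval[sdv == 0] <- 0
  zmap(tval, geometry, df = s - 1L)
}

#' Convert a t-map to z scores
#'
#' Probability-integral transform `z = qnorm(pt(t, df))`, evaluated in the
#' numerically safe tail so large statistics do not saturate.
#'
#' @param z A [zmap()] with finite `df`.
#' @return A [zmap()] of z scores with `df = NA`.
#' @export
t_to_z <- function(z) {
  stopifnot(inherits(z, "zmap"))
  if (is.na(z$df)) stop("map has no degrees of freedom: already z?")
  tv <- z$values
  out <- sign(tv) * stats::qnorm(stats::pt(abs(tv), df = z$df, lower.tail = FALSE),
                                 lower.tail = FALSE)
  zmap(out, z$geometry, df = NA_integer_)
}

neighborhood_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 `6`  = rowSums(abs(offs)) == 1,
                 `18` = rowSums(abs(offs)) <= 2,
                 `26` = rep(TRUE, nrow(offs)),
                 stop("connectivity must be 6, 18 or 26"))
  offs[keep, , drop = FALSE]
}

# connected components of TRUE voxels in a 3D logical array; returns integer
# label array (0 = background)
label_components <- function(mask3d, connectivity = 26L) {
  dims <- dim(mask3d)
  offs <- neighborhood_offsets(connectivity)
  labels <- array(0L, dims)
  idx <- which(mask3d)
  if (length(idx) == 0L) return(labels)
  in_set <- array(FALSE, dims)
  in_set[idx] <- TRUE
  current <- 0L
  for (seed in idx) {
    if (labels[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    labels[seed] <- current
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      cv <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        cu <- cv + offs[k, ]
        if (any(cu < 1L) || any(cu > dims)) next
        u <- cu[1] + dims[1] * (cu[2] - 1L) + dims[1] * dims[2] * (cu[3] - 1L)
        if (in_set[u] && labels[u] == 0L) {
          labels[u] <- current
          queue <- c(queue, u)
        }
      }
    }
  }
  labels
}

#' Construct a cluster report
#'
#' @param clusters A data frame with columns `label`, `size_voxels`,
#'   `size_mm3`, `peak_value`, `peak_x`, `peak_y`, `peak_z`, `significant`.
#' @param z_threshold Cluster-forming threshold used.
#' @param alpha Significance level (NA before correction).
#' @param null_summary List of null-derived thresholds (NULL before
#'   correction).
#' @return An object of class `cluster_report`.
#' @export
cluster_report <- function(clusters, z_threshold, alpha = NA_real_,
                           null_summary = NULL) {
  structure(list(clusters = clusters, z_threshold = z_threshold,
                 alpha = alpha, null_summary = null_summary),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d cluster(s) above z = %.3g", nrow(x$clusters),
              x$z_threshold))
  if (!is.na(x$alpha)) {
    cat(sprintf(", %d significant at alpha = %g",
                sum(x$clusters$significant), x$alpha))
  }
  cat("\n")
  if (nrow(x$clusters) > 0) print(utils::head(x$clusters, 10L))
  invisible(x)
}

#' Label suprathreshold clusters in a statistic map
#'
#' Connected components of voxels with `value > z_threshold` under the
#' requested connectivity. One tail at a time: run again on the negated map
#' for the negative tail.
#'
#' @param z A [zmap()].
#' @param z_threshold Positive cluster-forming threshold.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners, default).
#' @return A [cluster_report()] with `significant = NA` (pre-correction).
#'   Peak coordinates are 1-based grid indices.
#' @export
label_clusters <- function(z, z_threshold, connectivity = 26L) {
  stopifnot(inherits(z, "zmap"))
  if (z_threshold <= 0) stop("z_threshold must be positive")
  geom <- z$geometry
  arr <- unmask(z$values, geom, background = -Inf)
  supra <- arr > z_threshold
  labels <- label_components(supra, connectivity)
  n_clusters <- max(labels)
  vox_vol <- prod(geom$voxel_size)
  rows <- lapply(seq_len(n_clusters), function(lab) {
    idx <- which(labels == lab)
    vals <- arr[idx]
    peak <- idx[which.max(vals)]
    pc <- arrayInd(peak, geom$shape)
    data.frame(label = lab, size_voxels = length(idx),
               size_mm3 = length(idx) * vox_vol, peak_value = max(vals),
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
               significant = NA)
  })
  clusters <- if (n_clusters > 0) do.call(rbind, rows) else
    data.frame(label = integer(0), size_voxels = integer(0),
               size_mm3 = numeric(0), peak_value = numeric(0),
               peak_x = integer(0), peak_y = integer(0), peak_z = integer(0),
               significant = logical(0))
  cluster_report(clusters, z_threshold)
}

# Separable Gaussian smoothing along the three axes via small banded
# matrices; rows are L2-normalized so white noise keeps unit variance
# everywhere (including near edges).
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    s[i, j[ok]] <- k[ok]
    s[i, ] <- s[i, ] / sqrt(sum(s[i, ]^2))
  }
  s
}

gaussian_smooth_3d <- function(arr, sigma_voxels) {
  dims <- dim(arr)
  for (ax in 1:3) {
    if (sigma_voxels[ax] <= 0) next
    s <- smoothing_matrix(dims[ax], sigma_voxels[ax])
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    arr <- array(s %*% matrix(arr, dims[ax]), dim(arr))
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Equivalent Gaussian FWHM of a set of maps by correlation-area matching.
#
# Cluster-extent inference is governed by the correlation area (the integral
# of the spatial ACF), so the Gaussian null is matched on that functional
# rather than on the lag-1 autocorrelation alone: for kernel sd s (voxels),
# smoothed white noise has ACF exp(-d^2 / (4 s^2)) whose sum over d >= 1 is
# ~ s sqrt(pi) - 1/2. Averages the per-axis, per-map ACF at voxel lags
# 1..max_lag. Used by the test/acceptance layer to supply monte_carlo_null()
# with a data-matched smoothness; deliberately not exported - the public
# contract keeps the FWHM user-supplied.
estimate_equivalent_fwhm <- function(maps, geometry, max_lag = 4L) {
  acf_lag <- function(arr, ax, lag) {
    a <- aperm(arr, c(ax, setdiff(1:3, ax)))
    d1 <- dim(a)[1]
    if (lag >= d1) return(NA_real_)
    v1 <- a[seq_len(d1 - lag), , ]
    v2 <- a[(1 + lag):d1, , ]
    ok <- !is.na(v1) & !is.na(v2)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(v1[ok], v2[ok])
  }
  rho <- sapply(seq_len(max_lag), function(l) {
    mean(vapply(maps, function(v) {
      arr <- unmask(v, geometry, background = NA)
      mean(vapply(1:3, acf_lag, 0, arr = arr, lag = l), na.rm = TRUE)
    }, 0), na.rm = TRUE)
  })
  area <- sum(pmax(rho, 0))
  sigma_vox <- max((area + 0.5) / sqrt(pi), 0)
  2 * sqrt(2 * log(2)) * sigma_vox * mean(geometry$voxel_size)
}

#' Monte-Carlo null distribution of cluster size and peak
#'
#' Simulates the distribution of the maximum suprathreshold cluster size and
#' maximum cluster peak under the null: per iteration, Gaussian white noise
#' on the grid is smoothed with a Gaussian kernel of the stated FWHM,
#' restandardized to zero mean / unit variance inside the mask, thresholded
#' at `z_threshold`, and the largest cluster size and peak are recorded
#' (0 when no voxel survives).
#'
#' @param geometry A [mask_geometry()].
#' @param smoothness_fwhm_mm Full width at half maximum of the smoothing
#'   kernel in mm (0 = unsmoothed noise). Should reflect the spatial
#'   smoothness of the maps being corrected, e.g. the preprocessing kernel.
#' @param z_threshold Cluster-forming threshold.
#' @param n_iterations Number of simulations (>= 100).
#' @param seed RNG seed; the run is reproducible given the seed.
#' @param connectivity Cluster connectivity (default 26).
#' @return An object of class `null_distribution` with `max_sizes`,
#'   `max_peaks`, `n_iterations`, `smoothness_fwhm_mm`, `z_threshold`,
#'   `connectivity`.
#' @export
monte_carlo_null <- function(geometry, smoothness_fwhm_mm, z_threshold,
                             n_iterations = 1000L, seed = 1L,
                             connectivity = 26L) {
  if (n_iterations < 100L) stop("n_iterations must be >= 100")
  if (smoothness_fwhm_mm < 0) stop("fwhm must be >= 0")
  if (geometry$n < 2L) stop("degenerate mask")
  sigma_vox <- (smoothness_fwhm_mm / (2 * sqrt(2 * log(2)))) / geometry$voxel_size
  dims <- geometry$shape
  in_mask <- geometry$mask_linear
  max_sizes <- integer(n_iterations)
  max_peaks <- numeric(n_iterations)
  set.seed(seed)
  for (i in seq_len(n_iterations)) {
    noise <- array(stats::rnorm(prod(dims)), dims)
    if (any(sigma_vox > 0)) noise <- gaussian_smooth_3d(noise, sigma_vox)
    v <- noise[in_mask]
    v <- (v - mean(v)) / stats::sd(v)
    zm <- zmap(v, geometry)
    rep_i <- label_clusters(zm, z_threshold, connectivity)
    if (nrow(rep_i$clusters) > 0) {
      max_sizes[i] <- max(rep_i$clusters$size_voxels)
      max_peaks[i] <- max(rep_i$clusters$peak_value)
    }
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 max_sizes = max_sizes, max_peaks = max_peaks,
                 smoothness_fwhm_mm = smoothness_fwhm_mm,
                 z_threshold = z_threshold, connectivity = connectivity),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution: %d iterations, fwhm %g mm, z > %.3g; size q95 = %g, peak q95 = %.3g\n",
    x$n_iterations, x$smoothness_fwhm_mm, x$z_threshold,
    stats::quantile(x$max_sizes, 0.95, type = 1),
    stats::quantile(x$max_peaks, 0.95, type = 1)))
  invisible(x)
}

#' Apply Monte-Carlo cluster correction
#'
#' A cluster is significant if its size exceeds the `(1 - alpha/2)` quantile
#' of the null maximum cluster sizes OR its peak exceeds the `(1 - alpha/2)`
#' quantile of the null maximum peaks — a Bonferroni split across the two
#' criteria, so a large cluster with a moderate peak and a small cluster
#' with a very high peak can both reach significance.
#'
#' @param report A [label_clusters()] result.
#' @param null A [monte_carlo_null()] result with matching `z_threshold`.
#' @param alpha Family-wise level in `(0, 0.5]`.
#' @return The report with `significant` filled in, `alpha` set, and the
#'   null thresholds recorded in `null_summary`.
#' @export
apply_cluster_correction <- function(report, null, alpha = 0.05) {
  stopifnot(inherits(report, "cluster_report"),
            inherits(null, "null_distribution"))
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]")
  need <- ceiling(2 / alpha)
  if (null$n_iterations < need) {
    stop("null has ", null$n_iterations, " iterations; the 1 - alpha/2 = ",
         1 - alpha / 2, " quantile needs at least ", need)
  }
  size_thr <- stats::quantile(null$max_sizes, 1 - alpha / 2, type = 1, names = FALSE)
  peak_thr <- stats::quantile(null$max_peaks, 1 - alpha / 2, type = 1, names = FALSE)
  cl <- report$clusters
  cl$significant <- cl$size_voxels > size_thr | cl$peak_value > peak_thr
  cluster_report(cl, report$z_threshold, alpha = alpha,
                 null_summary = list(size_threshold_voxels = size_thr,
                                     peak_threshold = peak_thr,
                                     n_iterations = null$n_iterations,
                                     smoothness_fwhm_mm = null$smoothness_fwhm_mm))
}

#' Filter a cluster report by cluster volume
#'
#' Drops clusters at or below the volume floor and orders the rest by size
#' descending.
#'
#' @param report A [cluster_report()].
#' @param min_size_mm3 Volume floor in mm^3 (strictly-larger-than rule).
#' @return The filtered [cluster_report()].
#' @export
filter_report <- function(report, min_size_mm3 = 0) {
  stopifnot(inherits(report, "cluster_report"))
  if (min_size_mm3 < 0) stop("min_size_mm3 must be >= 0")
  cl <- report$clusters
  cl <- cl[cl$size_mm3 > min_size_mm3, , drop = FALSE]
  cl <- cl[order(-cl$size_voxels), , drop = FALSE]
  rownames(cl) <- NULL
  cluster_report(cl, report$z_threshold, alpha = report$alpha,
                 null_summary = report$null_summary)
}
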