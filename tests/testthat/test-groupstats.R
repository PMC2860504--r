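toy_geometry <- function(shape = c(6L, 6L, 4L), full = TRUE, vox = c(3, 3, 3)) {
  inside <- array(full, shape)
  if (!full) inside[sample.int(prod(shape), prod(shape) %/% 2)] <- TRUE
  mask_geometry(inside, voxel_size = vox)
}

test_that("gaussianize is rank-preserving, fixed on normal quantiles, and normalizes", {
  out <- gaussianize(c(3, 1, 2))
  expect_true(out[2] < out[3] && out[3] < out[1])

  # exact fixed point: inputs already at the (r - 0.5)/n normal quantiles
  n <- 40
  q <- qnorm((1:n - 0.5) / n)
  shuffled <- sample(q)
  expect_equal(gaussianize(shuffled), shuffled, tolerance = 1e-12)

  # mean and sd are restored
  set.seed(43)
  v <- rexp(200)
  g <- gaussianize(v)
  expect_equal(mean(g), mean(v))
  expect_equal(sd(g), sd(v))
  expect_equal(rank(g), rank(v))

  # lognormal sample passes a KS normality check after the transform
  set.seed(44)
  ln <- rlnorm(1000)
  gl <- gaussianize(ln)
  ks <- ks.test(gl, "pnorm", mean = mean(gl), sd = sd(gl))
  expect_gt(ks$p.value, 0.01)

  # idempotent up to rescaling on tie-free input
  expect_equal(gaussianize(gl), gl, tolerance = 1e-10)
  expect_error(gaussianize(rep(2, 10)), "equal")
})

test_that("paired_t_map computes the paired statistic with degenerate handling", {
  geom <- toy_geometry(c(3L, 3L, 2L))
  n <- geom$n
  set.seed(47)
  maps <- replicate(4, rnorm(n), simplify = FALSE)
  z0 <- paired_t_map(maps, maps, geom)
  expect_equal(z0$values, rep(0, n))
  expect_equal(z0$df, 3L)

  # hand oracle at one voxel: differences (1, 2, 0, 1, 1)
  d <- c(1, 2, 0, 1, 1)
  a5 <- lapply(d, function(x) c(x, rnorm(n - 1)))
  b5 <- lapply(seq_along(d), function(i) c(0, a5[[i]][-1] - rnorm(n - 1)))
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(paired_t_map(a5, b5, geom)$values[1], t_oracle)

  # constant nonzero differences: flagged and set to 0
  a_c <- replicate(3, c(5, rnorm(n - 1)), simplify = FALSE)
  b_c <- lapply(a_c, function(v) c(v[1] - 1, rnorm(n - 1)))
  expect_warning(zc <- paired_t_map(a_c, b_c, geom), "zero-variance")
  expect_equal(zc$values[1], 0)

  # antisymmetry
  aa <- replicate(5, rnorm(n), simplify = FALSE)
  bb <- replicate(5, rnorm(n), simplify = FALSE)
  expect_equal(paired_t_map(aa, bb, geom)$values,
               -paired_t_map(bb, aa, geom)$values)
  expect_error(paired_t_map(aa, bb[1:3], geom), "equal subject counts")
})

test_that("t_to_z matches the probability integral transform", {
  geom <- toy_geometry(c(3L, 2L, 2L))
  tv <- c(-4, -1, 0, 0.5, 2.33, 6, rnorm(geom$n - 6))
  z <- t_to_z(zmap(tv, geom, df = 9L))
  expect_equal(pnorm(z$values), pt(tv, df = 9), tolerance = 1e-12)
  expect_equal(z$values[3], 0)
  expect_true(all(abs(z$values[tv > 0]) < abs(tv[tv > 0])))
})

test_that("label_clusters finds connected components with sizes and peaks", {
  geom <- toy_geometry(c(8L, 8L, 4L))
  vals <- rep(0, geom$n)
  coords <- mask_coordinates(geom)
  blob1 <- which(coords[, 1] <= 3 & coords[, 2] <= 2 & coords[, 3] == 1)[1:5]
  blob2 <- which(coords[, 1] >= 6 & coords[, 2] >= 6 & coords[, 3] >= 3)[1:7]
  vals[blob1] <- 3
  vals[blob2] <- c(rep(3, 6), 5)
  rep_ <- label_clusters(zmap(vals, geom), 2.33)
  expect_equal(nrow(rep_$clusters), 2L)
  expect_setequal(rep_$clusters$size_voxels, c(5L, 7L))
  expect_equal(rep_$clusters$size_mm3, rep_$clusters$size_voxels * 27)
  expect_equal(max(rep_$clusters$peak_value), 5)
  expect_equal(sum(rep_$clusters$size_voxels), sum(vals > 2.33))

  # all subthreshold and single-voxel cases
  expect_equal(nrow(label_clusters(zmap(rep(0, geom$n), geom), 2.33)$clusters), 0L)
  single <- replace(rep(0, geom$n), 10, 4)
  r1 <- label_clusters(zmap(single, geom), 2.33)
  expect_equal(r1$clusters$size_voxels, 1L)
  expect_equal(r1$clusters$peak_value, 4)

  # 6- vs 26-connectivity: a diagonal pair is one cluster only under 26
  diagpair <- rep(0, geom$n)
  i1 <- which(coords[, 1] == 4 & coords[, 2] == 4 & coords[, 3] == 2)
  i2 <- which(coords[, 1] == 5 & coords[, 2] == 5 & coords[, 3] == 3)
  diagpair[c(i1, i2)] <- 3
  expect_equal(nrow(label_clusters(zmap(diagpair, geom), 2.33, 26L)$clusters), 1L)
  expect_equal(nrow(label_clusters(zmap(diagpair, geom), 2.33, 6L)$clusters), 2L)
})

test_that("monte_carlo_null is reproducible and responds to fwhm and threshold", {
  geom <- toy_geometry(c(8L, 8L, 6L))
  n1 <- monte_carlo_null(geom, 0, 2.33, 150, seed = 5)
  n2 <- monte_carlo_null(geom, 0, 2.33, 150, seed = 5)
  expect_identical(n1$max_sizes, n2$max_sizes)
  expect_identical(n1$max_peaks, n2$max_peaks)

  # extreme threshold: survivors essentially never occur
  n_hi <- monte_carlo_null(geom, 0, 5, 100, seed = 6)
  expect_gte(mean(n_hi$max_sizes == 0), 0.95)

  # smoothing increases cluster extent
  n_smooth <- monte_carlo_null(geom, 6, 2.33, 300, seed = 7)
  n_rough <- monte_carlo_null(geom, 0, 2.33, 300, seed = 7)
  q95 <- function(x) quantile(x, 0.95, type = 1)
  expect_gt(q95(n_smooth$max_sizes), q95(n_rough$max_sizes))
  expect_error(monte_carlo_null(geom, 0, 2.33, 50), ">= 100")
})

test_that("cluster correction applies the size-OR-peak rule", {
  geom <- toy_geometry(c(6L, 6L, 4L))
  null <- structure(list(n_iterations = 200L,
                         max_sizes = rep(c(0L, 1L, 2L, 10L), c(100, 60, 36, 4)),
                         max_peaks = c(rep(3.5, 195), rep(6, 5)),
                         smoothness_fwhm_mm = 0, z_threshold = 2.33,
                         connectivity = 26L),
                    class = "null_distribution")
  clusters <- data.frame(
    label = 1:3, size_voxels = c(50L, 1L, 2L),
    size_mm3 = c(50, 1, 2) * 27, peak_value = c(2.8, 7.0, 2.9),
    peak_x = 1:3, peak_y = 1:3, peak_z = 1:3, significant = NA)
  rep_ <- cluster_report(clusters, 2.33)
  out <- apply_cluster_correction(rep_, null, alpha = 0.05)
  # size threshold = 97.5% quantile of max sizes (=2), peak threshold = 6
  expect_true(out$clusters$significant[1])    # big cluster, modest peak
  expect_true(out$clusters$significant[2])    # tiny cluster, extreme peak
  expect_false(out$clusters$significant[3])   # neither
  expect_equal(out$null_summary$size_threshold_voxels, 2)
  expect_equal(out$null_summary$peak_threshold, 3.5)
  expect_error(apply_cluster_correction(rep_, null, alpha = 0.005), "at least")
})

test_that("filter_report drops small clusters and orders by size", {
  clusters <- data.frame(
    label = 1:3, size_voxels = c(5L, 2L, 9L),
    size_mm3 = c(150, 90, 250), peak_value = c(3, 4, 5),
    peak_x = 1, peak_y = 1, peak_z = 1, significant = TRUE)
  rep_ <- cluster_report(clusters, 2.33, alpha = 0.05)
  out <- filter_report(rep_, 100)
  expect_equal(out$clusters$label, c(3L, 1L))
  expect_equal(nrow(filter_report(rep_, 0)$clusters), 3L)
  expect_equal(nrow(filter_report(rep_, 1000)$clusters), 0L)
})

test_that("null quantiles are monotone in alpha and fwhm", {
  geom <- toy_geometry(c(8L, 8L, 6L))
  fw <- c(0, 4, 8)
  nulls <- lapply(fw, function(f) monte_carlo_null(geom, f, 2.33, 200, seed = 11))
  qs <- function(nd, p) quantile(nd$max_sizes, p, type = 1)
  for (nd in nulls) {
    expect_true(qs(nd, 0.99) >= qs(nd, 0.95))   # smaller alpha, larger threshold
  }
  expect_true(qs(nulls[[2]], 0.95) >= qs(nulls[[1]], 0.95))
  expect_true(qs(nulls[[3]], 0.95) >= qs(nulls[[2]], 0.95))
})
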