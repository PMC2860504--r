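# Shared fixtures and independent oracles.

# random symmetric non-negative matrix with strictly positive off-diagonals
random_similarity <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n * n, min = 0.01, max = 1), n, n)
  a <- (m + t(m)) / 2
  diag(a) <- 1
  a
}

# dense eigendecomposition oracle for the dominant eigenvector, sign fixed
# entrywise non-negative
eigen_oracle <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  list(vector = v, value = max(e$values))
}

# brute-force betweenness oracle: enumerate every simple path between every
# pair, keep shortest (by hops or total length), count pass-throughs
brute_betweenness <- function(adj, len = NULL) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (u in which(adj[v, ])) {
        if (!(u %in% path)) walk(c(path, u))
      }
    }
    walk(s)
    out
  }
  path_len <- function(p) {
    if (is.null(len)) return(length(p) - 1)
    sum(vapply(seq_len(length(p) - 1), function(i) len[p[i], p[i + 1]], 0))
  }
  cb <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, path_len, 0)
      shortest <- paths[lens < min(lens) + 1e-12]
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
        cb[v] <- cb[v] + through / length(shortest)
      }
    }
  }
  cb / ((n - 1) * (n - 2) / 2)
}

# similarity matrix whose graph (after threshold 0) is a given 0/1 adjacency
adjacency_similarity <- function(adj, weights = NULL) {
  a <- if (is.null(weights)) adj * 1 else weights
  diag(a) <- 1
  similarity_matrix(nrow(adj), "dense", dense = a, metric = "fixture")
}

# small synthetic NIfTI pair (bold + mask) on disk; returns the paths
write_bold_fixture <- function(dir, grid = c(6L, 6L, 4L), t_len = 40L,
                               n_mask = 30L, tr = 2.3, seed = 1L) {
  set.seed(seed)
  bold <- array(rnorm(prod(grid) * t_len), c(grid, t_len))
  inside <- array(FALSE, grid)
  inside[sample.int(prod(grid), n_mask)] <- TRUE
  affine <- diag(c(3, 3, 3, 1)); affine[1:3, 4] <- c(-9, -9, -6)
  bold_path <- file.path(dir, "bold.nii.gz")
  mask_path <- file.path(dir, "mask.nii.gz")
  write_nifti(bold, bold_path, affine = affine, voxel_size = c(3, 3, 3),
              tr_seconds = tr)
  write_nifti(array(as.double(inside), grid), mask_path, affine = affine,
              voxel_size = c(3, 3, 3))
  list(bold = bold_path, mask = mask_path, inside = inside, data = bold)
}

# per-subject ECM pipeline used by group-level tests: factored scaled
# correlation -> eigenvector centrality -> Gaussianization
subject_ecm <- function(series) {
  A <- correlation_similarity(series, "scaled", "factored")
  gaussianize(eigenvector_centrality(A)$values)
}
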