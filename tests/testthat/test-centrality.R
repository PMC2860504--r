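test_that("degree_centrality sums off-diagonal similarities", {
  a4 <- matrix(1, 4, 4)
  A <- similarity_matrix(4, "dense", dense = a4)
  expect_equal(degree_centrality(A)$values, rep(3, 4))

  a3 <- diag(3); a3[1, 2] <- a3[2, 1] <- 0.5; a3[1, 3] <- a3[3, 1] <- 0.5
  A3 <- similarity_matrix(3, "dense", dense = a3)
  expect_equal(degree_centrality(A3)$values, c(1.0, 0.5, 0.5))

  # linear in the off-diagonal scale
  set.seed(13)
  a <- random_similarity(15)
  d1 <- degree_centrality(similarity_matrix(15, "dense", dense = a))$values
  a2 <- a * 2; diag(a2) <- diag(a)
  d2 <- degree_centrality(similarity_matrix(15, "dense", dense = a2))$values
  expect_equal(d2, 2 * d1)

  # factored path agrees with the dense path
  z <- matrix(rnorm(40 * 10), 40, 10)
  z <- z / sqrt(rowSums(z^2))
  Af <- similarity_matrix(40, "factored", factor = z)
  Ad <- similarity_matrix(40, "dense", dense = as_dense(Af))
  expect_equal(degree_centrality(Af)$values, degree_centrality(Ad)$values,
               tolerance = 1e-12)
})

test_that("power_iteration converges to the dominant eigenpair", {
  # diagonal operator: converges to the dominant axis
  res <- power_iteration(function(x) c(2, 1) * x, 2, tol = 1e-10)
  expect_equal(res$vector, c(1, 0), tolerance = 1e-8)
  expect_equal(res$value, 2, tolerance = 1e-8)

  # rank-one all-ones matrix: uniform vector in <= 2 iterations
  res1 <- power_iteration(function(x) rep(sum(x), 5), 5)
  expect_equal(res1$vector, rep(1 / sqrt(5), 5))
  expect_equal(res1$value, 5)
  expect_lte(res1$iterations, 2L)

  # dense eigensolver oracle on a random 200x200 instance
  a <- random_similarity(200, seed = 17)
  res2 <- power_iteration(function(x) drop(a %*% x), 200, tol = 1e-12)
  oracle <- eigen_oracle(a)
  expect_lt(max(abs(res2$vector - oracle$vector)), 1e-8)
  expect_equal(res2$value, oracle$value, tolerance = 1e-10)

  expect_error(power_iteration(function(x) c(2, 1) * x, 2, tol = 1e-10,
                               max_iter = 3L),
               "did not converge")
})

test_that("eigenvector_centrality satisfies the eigen equation and invariances", {
  # 2x2 symmetric: equal entries regardless of the off-diagonal value
  for (a_off in c(0.1, 0.5, 1)) {
    A <- similarity_matrix(2, "dense",
                           dense = matrix(c(1, a_off, a_off, 1), 2))
    expect_equal(eigenvector_centrality(A)$values, rep(1 / sqrt(2), 2),
                 tolerance = 1e-9)
  }

  # star-like: strongly tied center wins (checked against dense oracle)
  a <- matrix(0.1, 5, 5); diag(a) <- 1
  a[1, 2:5] <- a[2:5, 1] <- 0.9
  A <- similarity_matrix(5, "dense", dense = a)
  cm <- eigenvector_centrality(A)
  expect_true(all(cm$values[1] > cm$values[2:5]))
  expect_lt(max(abs(cm$values - eigen_oracle(a)$vector)), 1e-8)

  # residual bound: A x = lambda x within tol * lambda
  r <- random_similarity(60, seed = 19)
  Ar <- similarity_matrix(60, "dense", dense = r)
  cmr <- eigenvector_centrality(Ar, tol = 1e-11)
  expect_lt(max(abs(r %*% cmr$values - cmr$eigenvalue * cmr$values)),
            1e-8 * cmr$eigenvalue)
  # Perron property: strictly positive entries
  expect_true(all(cmr$values > 0))
  # scaling invariance: A and 2A give the same map
  cmr2 <- eigenvector_centrality(similarity_matrix(60, "dense", dense = 2 * r))
  expect_equal(cmr2$values, cmr$values, tolerance = 1e-9)
  # diagonal shift invariance
  cmr3 <- eigenvector_centrality(similarity_matrix(60, "dense",
                                                   dense = r + diag(60) * 0.7))
  expect_equal(cmr3$values, cmr$values, tolerance = 1e-8)

  # reducible matrix is refused
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 0.5
  expect_error(eigenvector_centrality(similarity_matrix(4, "dense", dense = bad)),
               "reducible")
})

test_that("permutation equivariance holds for all three centralities", {
  set.seed(23)
  a <- random_similarity(9)
  perm <- sample(9)
  ap <- a[perm, perm]
  A <- similarity_matrix(9, "dense", dense = a)
  Ap <- similarity_matrix(9, "dense", dense = ap)
  expect_equal(eigenvector_centrality(Ap)$values,
               eigenvector_centrality(A)$values[perm], tolerance = 1e-8)
  expect_equal(degree_centrality(Ap)$values,
               degree_centrality(A)$values[perm], tolerance = 1e-12)
  expect_equal(betweenness_centrality(Ap, edge_threshold = 0.5)$values,
               betweenness_centrality(A, edge_threshold = 0.5)$values[perm],
               tolerance = 1e-12)
})

test_that("betweenness matches hand values on path and star graphs", {
  path <- matrix(FALSE, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- TRUE
  A <- adjacency_similarity(path)
  expect_equal(betweenness_centrality(A, edge_threshold = 0.5)$values,
               c(0, 1, 0))

  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  As <- adjacency_similarity(star)
  expect_equal(betweenness_centrality(As, edge_threshold = 0.5)$values,
               c(1, 0, 0, 0, 0))
})

test_that("betweenness matches brute-force enumeration on random graphs", {
  set.seed(29)
  for (i in 1:6) {
    n <- sample(5:8, 1)
    adj <- matrix(FALSE, n, n)
    for (p in which(upper.tri(adj))) adj[p] <- runif(1) < 0.5
    adj <- adj | t(adj)
    # unweighted
    A <- adjacency_similarity(adj)
    expect_equal(betweenness_centrality(A, edge_threshold = 0.5)$values,
                 brute_betweenness(adj), tolerance = 1e-12)
    # weighted: distance = 1 - similarity
    w <- matrix(runif(n * n, 0.2, 0.9), n, n)
    w <- (w + t(w)) / 2
    w[!adj] <- 0
    Aw <- adjacency_similarity(adj, weights = w)
    expect_equal(
      betweenness_centrality(Aw, edge_threshold = 0.05,
                             weighting = "distance")$values,
      brute_betweenness(adj & (w > 0.05), len = 1 - w), tolerance = 1e-10)
  }
})

test_that("betweenness agrees with igraph and honors the node limit", {
  skip_if_not_installed("igraph")
  set.seed(31)
  n <- 12
  adj <- matrix(FALSE, n, n)
  for (p in which(upper.tri(adj))) adj[p] <- runif(1) < 0.4
  adj <- adj | t(adj)
  A <- adjacency_similarity(adj)
  ours <- betweenness_centrality(A, edge_threshold = 0.5)$values
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ref <- igraph::betweenness(g, normalized = TRUE)
  expect_equal(ours, unname(ref), tolerance = 1e-10)

  expect_error(betweenness_centrality(A, limit = 5L), "limit")
  expect_s3_class(betweenness_centrality(A, limit = 5L, force = TRUE),
                  "centrality_map")
})

test_that("scale dichotomy: degree scales, eigenvector does not", {
  set.seed(37)
  for (i in 1:5) {
    a <- random_similarity(25)
    s <- runif(1, 1.5, 5)
    a_s <- a * s
    A <- similarity_matrix(25, "dense", dense = a)
    As <- similarity_matrix(25, "dense", dense = a_s)
    expect_equal(degree_centrality(As)$values, s * degree_centrality(A)$values,
                 tolerance = 1e-12)
    expect_equal(eigenvector_centrality(As, tol = 1e-12)$values,
                 eigenvector_centrality(A, tol = 1e-12)$values,
                 tolerance = 1e-10)
  }
})
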