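# Node centrality over a similarity matrix.
#
# Eigenvector centrality is the Perron eigenvector of the (symmetric,
# non-negative, irreducible) similarity matrix: voxel i scores high when it
# is strongly similar to voxels that are themselves central. Degree
# centrality is the plain off-diagonal row sum; multiplying all similarities
# by s scales degree by s but leaves the eigenvector unchanged, which is why
# the two can disagree about global effects. Betweenness is the normalized
# shortest-path load and is only feasible on small node sets.

#' Construct a centrality map object
#'
#' @param values Non-negative per-voxel scores in mask order.
#' @param method `"eigenvector"`, `"degree"` or `"betweenness"`.
#' @param metric Provenance tag of the similarity metric.
#' @param iterations,eigenvalue Power-iteration diagnostics (eigenvector
#'   only).
#' @return An object of class `centrality_map`.
#' @export
centrality_map <- function(values, method, metric = "unknown",
                           iterations = NA_integer_, eigenvalue = NA_real_) {
  method <- match.arg(method, c("eigenvector", "degree", "betweenness"))
  if (any(values < -1e-12)) stop("centrality values must be non-negative")
  values <- pmax(values, 0)
  structure(list(values = values, method = method, metric = metric,
                 iterations = iterations, eigenvalue = eigenvalue),
            class = "centrality_map")
}

#' @export
print.centrality_map <- function(x, ...) {
  cat(sprintf("centrality_map: %s over %s, n = %d", x$method, x$metric,
              length(x$values)))
  if (x$method == "eigenvector") {
    cat(sprintf(", lambda = %.6g (%d iterations)", x$eigenvalue, x$iterations))
  }
  cat("\n")
  invisible(x)
}

#' Degree centrality
#'
#' Sum of similarities of each node to all other nodes; the diagonal
#' (self-similarity) is excluded — it contributes no connection.
#'
#' @param A A [similarity_matrix()], dense or factored.
#' @return A [centrality_map()] with `method = "degree"`.
#' @export
degree_centrality <- function(A) {
  stopifnot(inherits(A, "similarity_matrix"))
  if (A$form == "dense") {
    vals <- rowSums(A$dense) - diag(A$dense)
  } else {
    op <- similarity_operator(A)
    vals <- op(rep(1, A$n)) - (rowSums(A$factor^2) + 1) / 2
  }
  centrality_map(vals, "degree", metric = A$metric)
}

#' Power iteration for the dominant eigenpair
#'
#' Repeated application of a symmetric non-negative linear operator with
#' normalization. The start vector is the uniform positive vector
#' `1/sqrt(n)`: deterministic, and never orthogonal to the Perron vector of
#' an irreducible non-negative operator. Convergence is declared when the
#' max-norm change of the normalized iterate drops below `tol`.
#'
#' @param matvec Function taking and returning an `n`-vector, representing a
#'   symmetric non-negative irreducible matrix.
#' @param n Problem size.
#' @param tol Max-norm convergence tolerance on the normalized iterate.
#' @param max_iter Iteration cap; exceeding it is an error carrying the last
#'   residual.
#' @return List with `vector` (unit Euclidean norm, entrywise non-negative),
#'   `value` (Rayleigh quotient at convergence) and `iterations`.
#' @export
power_iteration <- function(matvec, n, tol = 1e-9, max_iter = 1000L) {
  v <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- matvec(v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("operator annihilated the iterate; matrix not irreducible?")
    v_new <- w / nw
    if (sum(v_new) < 0) v_new <- -v_new
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) {
      lambda <- sum(v * matvec(v))
      return(list(vector = pmax(v, 0) / sqrt(sum(pmax(v, 0)^2)),
                  value = lambda, iterations = it))
    }
  }
  stop(sprintf("power iteration did not converge in %d iterations (last residual %.3g)",
               max_iter, max(abs(matvec(v) / sqrt(sum(matvec(v)^2)) - v))))
}

#' Eigenvector centrality
#'
#' Entries of the unit-norm eigenvector belonging to the largest eigenvalue
#' of the similarity matrix, computed by power iteration (matrix-free for the
#' factored form). For irreducible non-negative `A` the Perron-Frobenius
#' theorem guarantees this eigenvector is unique and entrywise non-negative;
#' irreducibility is checked before iterating. The diagonal of `A` is kept as
#' computed — adding `c I` shifts every eigenvalue by `c` and leaves the
#' eigenvector unchanged, so the choice is immaterial.
#'
#' @param A A [similarity_matrix()].
#' @param tol,max_iter Passed to [power_iteration()].
#' @return A [centrality_map()] with `method = "eigenvector"`, the dominant
#'   eigenvalue and the iteration count.
#' @export
eigenvector_centrality <- function(A, tol = 1e-9, max_iter = 1000L) {
  stopifnot(inherits(A, "similarity_matrix"))
  check_irreducible(A)
  res <- power_iteration(similarity_operator(A), A$n, tol = tol,
                         max_iter = max_iter)
  centrality_map(res$vector, "eigenvector", metric = A$metric,
                 iterations = res$iterations, eigenvalue = res$value)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node,
#' normalized by the `(n-1)(n-2)/2` pairs not containing it, via Brandes'
#' accumulation. Similarities are first thresholded: pairs with
#' `a_ij > edge_threshold` become edges. In `"unweighted"` mode every edge
#' has unit length (BFS); in `"distance"` mode the edge length is
#' `1 - a_ij` (Dijkstra), so stronger similarity means shorter distance.
#' Disconnected pairs contribute nothing. Quadratic-to-cubic cost makes this
#' infeasible at voxel scale, so node counts above `limit` are refused
#' unless `force = TRUE`.
#'
#' @param A A [similarity_matrix()] (materialized if factored).
#' @param edge_threshold Similarity level above which an edge exists.
#' @param weighting `"unweighted"` or `"distance"`.
#' @param limit Soft node-count limit (default 5000).
#' @param force Override the limit.
#' @return A [centrality_map()] with values in `[0, 1]`.
#' @export
betweenness_centrality <- function(A, edge_threshold = 0,
                                   weighting = c("unweighted", "distance"),
                                   limit = 5000L, force = FALSE) {
  stopifnot(inherits(A, "similarity_matrix"))
  weighting <- match.arg(weighting)
  n <- A$n
  if (n > limit && !force) {
    stop("n = ", n, " exceeds the betweenness limit ", limit,
         " (computation is infeasible at voxel scale); use force = TRUE")
  }
  a <- as_dense(A)
  adj <- a > edge_threshold
  diag(adj) <- FALSE
  len <- if (weighting == "distance") 1 - a else (adj * 1)
  cb <- numeric(n)
  eps <- 1e-12

  for (s in seq_len(n)) {
    # single-source shortest paths with path counts
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    if (weighting == "unweighted") {
      order_visited <- integer(0)
      frontier <- s
      while (length(frontier) > 0L) {
        order_visited <- c(order_visited, frontier)
        nxt <- integer(0)
        for (v in frontier) {
          nbrs <- which(adj[v, ])
          for (u in nbrs) {
            if (is.infinite(dist[u])) {
              dist[u] <- dist[v] + 1
              nxt <- c(nxt, u)
            }
            if (dist[u] == dist[v] + 1) {
              sigma[u] <- sigma[u] + sigma[v]
              preds[[u]] <- c(preds[[u]], v)
            }
          }
        }
        frontier <- unique(nxt)
      }
    } else {
      done <- logical(n)
      order_visited <- integer(0)
      repeat {
        cand <- which(!done & is.finite(dist))
        if (length(cand) == 0L) break
        v <- cand[which.min(dist[cand])]
        done[v] <- TRUE
        order_visited <- c(order_visited, v)
        for (u in which(adj[v, ] & !done)) {
          alt <- dist[v] + len[v, u]
          if (alt < dist[u] - eps) {
            dist[u] <- alt
            sigma[u] <- sigma[v]
            preds[[u]] <- v
          } else if (abs(alt - dist[u]) <= eps) {
            sigma[u] <- sigma[u] + sigma[v]
            preds[[u]] <- c(preds[[u]], v)
          }
        }
      }
    }
    # Brandes back-propagation of pair dependencies
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) cb[v] <- cb[v] + delta[v]
    }
  }
  # each unordered (s, t) pair was accumulated from both endpoints
  cb <- cb / 2
  norm <- (n - 1) * (n - 2) / 2
  centrality_map(if (norm > 0) cb / norm else cb, "betweenness",
                 metric = A$metric)
}
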