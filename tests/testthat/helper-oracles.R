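# Independent oracles, written from first principles and kept deliberately
# separate from the implementation paths they check.

# Dense all-pairs shortest paths over a weight matrix with Inf for missing
# edges; triple loop, no graph library.
floyd_warshall <- function(W) {
  n <- nrow(W)
  d <- W
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Neighbor-graph weight matrix (Inf where no edge) by direct thresholding.
threshold_weights <- function(D, r) {
  W <- matrix(Inf, nrow(D), ncol(D))
  W[D < r] <- D[D < r]
  diag(W) <- 0
  W
}

# Prim's MST on a complete graph from scratch; returns the n-1 edges.
prim_mst <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  w <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    best <- c(NA, NA); bw <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree))
      if (D[i, j] < bw) { bw <- D[i, j]; best <- c(i, j) }
    edges[k, ] <- best
    w[k] <- bw
    in_tree[best[2]] <- TRUE
  }
  list(edges = edges, weights = w)
}

# Classical PCoA from scratch: double-center -D^2/2 and eigendecompose.
pcoa_oracle <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-9
  list(coordinates = e$vectors[, keep, drop = FALSE] %*%
         diag(sqrt(e$values[keep]), sum(keep)),
       eigenvalues = e$values[keep])
}

# Adjusted Fisher-Pearson skewness by direct moments.
skewness_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2)^1.5)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Random valid distance matrices.
random_distance_matrix <- function(n, max_val = 1) {
  M <- matrix(runif(n * n, 0.05, max_val), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  M
}

# Metric matrices: Euclidean distances of a random point cloud.
random_metric_matrix <- function(n, d = 3) {
  as_distance_matrix(as.matrix(dist(matrix(rnorm(n * d), n, d))))
}

# Two well-separated Gaussian blobs; distances are right-skewed because
# within-cluster pairs dominate the low end.
simulate_gaussian_blobs <- function(n_per = 30, dims = 5, sep = 3) {
  X <- rbind(matrix(rnorm(n_per * dims), n_per, dims),
             matrix(rnorm(n_per * dims, mean = sep), n_per, dims))
  as_distance_matrix(as.matrix(dist(X)))
}
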