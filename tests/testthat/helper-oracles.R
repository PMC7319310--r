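# Independent oracles used across the suite.  Each one recomputes a
# quantity by a different route than the package implementation
# (brute-force loops, adjacency enumeration, proximal-gradient
# optimization) so agreement is evidence, not tautology.

# Brute-force discrete gradient: a double loop over the four-case
# definition, no vectorization shared with gradient_image().
oracle_gradient <- function(B) {
  p <- nrow(B); q <- ncol(B)
  g <- array(0, dim = c(p, q, 2))
  for (j in seq_len(p)) {
    for (k in seq_len(q)) {
      g[j, k, 1] <- if (j < p) B[j + 1, k] - B[j, k] else 0
      g[j, k, 2] <- if (k < q) B[j, k + 1] - B[j, k] else 0
    }
  }
  g
}

# Grid-graph Laplacian built directly from the 4-neighbour adjacency
# structure, never touching the difference-matrix index formula.
oracle_lattice_laplacian <- function(p, q) {
  m <- p * q
  A <- matrix(0, m, m)
  idx <- function(j, k) p * (k - 1) + j
  for (j in seq_len(p)) {
    for (k in seq_len(q)) {
      if (j < p) { A[idx(j, k), idx(j + 1, k)] <- 1
                   A[idx(j + 1, k), idx(j, k)] <- 1 }
      if (k < q) { A[idx(j, k), idx(j, k + 1)] <- 1
                   A[idx(j, k + 1), idx(j, k)] <- 1 }
    }
  }
  diag(rowSums(A)) - A
}

# Rows of D as a canonical set of signed pixel-pair differences,
# enumerated from adjacency (order-free representation).
oracle_edge_set <- function(p, q) {
  idx <- function(j, k) p * (k - 1) + j
  edges <- list()
  for (k in seq_len(q)) {
    for (j in seq_len(p)) {
      if (j < p) edges[[length(edges) + 1]] <- c(idx(j, k), idx(j + 1, k))
      if (k < q) edges[[length(edges) + 1]] <- c(idx(j, k), idx(j, k + 1))
    }
  }
  mat <- do.call(rbind, edges)
  mat[order(mat[, 1], mat[, 2]), , drop = FALSE]
}

# FISTA (accelerated proximal gradient) minimizer of the penalized
# logistic objective.  An independent algorithm family from coordinate
# descent; run long with a conservative step for tiny instances.
oracle_fista <- function(data, penalty, op, max_iter = 30000,
                         tol = 1e-14) {
  X <- data$X; y <- data$y
  n <- nrow(X); m <- ncol(X)
  K <- as.matrix(op$K)
  l1 <- penalty$lambda1; l2 <- penalty$lambda2
  # Lipschitz bound for the smooth part's gradient
  L <- svd(X, nu = 0, nv = 0)$d[1]^2 / (4 * n) +
    2 * l1 * max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  grad_smooth <- function(b) {
    pr <- stats::plogis(y * drop(X %*% b))
    drop(crossprod(X, (pr - 1) * y)) / n + 2 * l1 * drop(K %*% b)
  }
  obj <- function(b) objective(b, data, penalty, op)
  b <- numeric(m); z <- b; t_k <- 1
  best <- b; best_obj <- obj(b)
  for (it in seq_len(max_iter)) {
    b_new <- soft_threshold(z - step * grad_smooth(z), step * l2)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    o <- obj(b_new)
    if (o < best_obj) { best <- b_new; best_obj <- o }
    if (it > 10 && max(abs(b_new - b)) < tol) break
    b <- b_new; t_k <- t_new
  }
  list(beta = best, objective = best_obj)
}

# A small random instance with nontrivial signal for solver tests.
random_instance <- function(seed, n = 40, p = 5, q = 5) {
  set.seed(seed)
  shape <- image_shape(p, q)
  X <- matrix(rnorm(n * p * q), n, p * q)
  beta0 <- numeric(p * q)
  beta0[sample(p * q, 3)] <- rnorm(3, sd = 1.5)
  y <- ifelse(runif(n) < plogis(drop(X %*% beta0)), 1, -1)
  labeled_image_dataset(X, y, shape)
}
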