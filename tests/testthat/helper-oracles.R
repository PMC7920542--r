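# Independent brute-force oracles used to validate the implementation.

# Double-loop evaluation of the fractional-scaling normalization.
oracle_fractional <- function(raw) {
  n <- nrow(raw)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      den <- 0
      for (x in seq_len(n)) if (x != i) den <- den + raw[i, x]
      for (y in seq_len(n)) if (y != j) den <- den + raw[y, j]
      out[i, j] <- if (den > 0) raw[i, j] / den else NA_real_
    }
  }
  out
}

# Floyd-Warshall all-pairs shortest paths on a logical adjacency matrix.
oracle_shortest_paths <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Triple-loop triangle counts.
oracle_triangles <- function(a) {
  n <- nrow(a)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        t_i[i] <- t_i[i] + (a[i, j] && a[i, h] && a[j, h]) / 2
      }
    }
  }
  t_i
}

# Double-loop modularity with the total-degree-sum normalizer.
oracle_modularity <- function(a, partition) {
  l2 <- sum(a)
  if (l2 == 0) return(NA_real_)
  k <- rowSums(a)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (partition[i] == partition[j]) {
        q <- q + (a[i, j] - k[i] * k[j] / l2)
      }
    }
  }
  q / l2
}

# Edge-list assortativity computed straight from the definition.
oracle_assortativity <- function(a) {
  k <- rowSums(a)
  e <- which(a & upper.tri(a), arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  ki <- k[e[, 1]]; kj <- k[e[, 2]]
  m1 <- mean(ki * kj)
  m2 <- mean((ki + kj) / 2)
  m3 <- mean((ki^2 + kj^2) / 2)
  (m1 - m2^2) / (m3 - m2^2)
}

# Random simple undirected graph on n nodes.
random_graph <- function(n, p = 0.45) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  a <- a & upper.tri(a)
  a <- a | t(a)
  diag(a) <- FALSE
  a
}

# Grid-search oracle for the exponential decay fit: lambda on a fixed grid,
# alpha profiled in closed form at each lambda.
oracle_decay_grid <- function(y, d, lambda_grid = seq(10, 40, by = 0.1)) {
  sse <- vapply(lambda_grid, function(l) {
    e <- exp(-d / l)
    a <- sum(y * e) / sum(e^2)
    sum((y - a * e)^2)
  }, numeric(1))
  lambda_grid[which.min(sse)]
}
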