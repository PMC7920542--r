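test_that("closed forms: clique, path and star graphs", {
  # K4: everything saturates at 1
  k4 <- binary_graph(matrix(1, 4, 4))
  nm <- node_metrics(k4)
  expect_equal(nm$clustering, rep(1, 4))
  expect_true(all(nm$distance[upper.tri(nm$distance)] == 1))
  gm <- graph_metrics(k4)
  expect_equal(gm$mcc, 1); expect_equal(gm$transitivity, 1)
  expect_equal(gm$cpl, 1); expect_equal(gm$efficiency, 1)
  expect_equal(gm$density, 1)
  # P3 path: nodal efficiencies from the definition
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
  p3 <- binary_graph(a)
  nmp <- node_metrics(p3)
  expect_equal(nmp$efficiency[1], (1 + 1 / 2) / 2)
  expect_equal(nmp$efficiency[2], 1)
  expect_equal(nmp$avg_distance, c(1.5, 1, 1.5))
  expect_equal(nmp$clustering, rep(0, 3))  # k<2 convention and no triangles
  # star: perfectly disassortative
  st <- matrix(0, 4, 4); st[1, 2:4] <- 1; st[2:4, 1] <- 1
  expect_equal(graph_metrics(binary_graph(st))$assortativity, -1)
})

test_that("all metrics equal brute-force oracles on random small graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    a <- random_graph(n, runif(1, 0.25, 0.75))
    g <- binary_graph(a)
    nm <- node_metrics(g)
    d_oracle <- oracle_shortest_paths(a)
    expect_equal(nm$distance, d_oracle)
    t_oracle <- oracle_triangles(a)
    expect_equal(nm$triangles, t_oracle)
    k <- rowSums(a)
    expect_equal(nm$degree, k)
    expect_equal(nm$clustering,
                 ifelse(k >= 2, 2 * t_oracle / (k * (k - 1)), 0))
    part <- sample(1:2, n, replace = TRUE)
    gm <- graph_metrics(g, partition = part)
    expect_equal(gm$q, oracle_modularity(a, part))
    denom <- sum(k * (k - 1))
    expect_equal(gm$transitivity,
                 if (denom > 0) sum(2 * t_oracle) / denom else 0)
    if (!is.na(gm$assortativity)) {
      expect_equal(gm$assortativity, oracle_assortativity(a))
    }
    expect_equal(gm$density, sum(a) / 2 / (n * (n - 1) / 2))
    # efficiency against the definition
    inv <- 1 / d_oracle
    inv[!is.finite(inv)] <- 0
    diag(inv) <- NA
    expect_equal(gm$efficiency, mean(rowMeans(inv, na.rm = TRUE)))
  }
})

test_that("modularity of two disjoint cliques matches the double loop", {
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1
  diag(a) <- 0
  part <- rep(1:2, each = 4)
  g <- binary_graph(a)
  expect_equal(graph_metrics(g, partition = part)$q,
               oracle_modularity(a > 0, part))
  expect_equal(graph_metrics(g, partition = part)$q, 0.5)
})

test_that("metrics are invariant to node relabelling", {
  set.seed(102)
  a <- random_graph(7, 0.5)
  p <- sample(7)
  g1 <- graph_metrics(binary_graph(a), partition = rep(1:7))
  g2 <- graph_metrics(binary_graph(a[p, p]), partition = rep(1:7)[p])
  for (f in c("mcc", "cpl", "efficiency", "q", "transitivity",
              "assortativity", "density")) {
    expect_equal(g1[[f]], g2[[f]], info = f)
  }
})

test_that("deleting an edge never increases triangles, transitivity or density", {
  set.seed(103)
  for (rep in 1:10) {
    a <- random_graph(7, 0.6)
    e <- which(a & upper.tri(a), arr.ind = TRUE)
    if (nrow(e) < 2) next
    pick <- e[sample(nrow(e), 1), ]
    a2 <- a; a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- FALSE
    nm1 <- node_metrics(binary_graph(a)); nm2 <- node_metrics(binary_graph(a2))
    expect_true(all(nm2$triangles <= nm1$triangles))
    g1 <- graph_metrics(binary_graph(a)); g2 <- graph_metrics(binary_graph(a2))
    expect_lte(g2$density, g1$density)
    # transitivity can only drop when the triangle count drops at fixed
    # degrees; assert the weaker monotone pair jointly
    expect_lte(sum(nm2$triangles), sum(nm1$triangles))
  }
})

test_that("null-normalized metrics are unity on their own ensemble", {
  set.seed(104)
  g <- binary_graph(random_graph(40, 0.25))
  nm <- normalized_metrics(g, null_model = "erdos_renyi", n_null = 30,
                           seed = 5)
  expect_equal(nm$small_worldness, nm$gamma / nm$lambda_norm)
  expect_lt(abs(nm$gamma - 1), 0.35)
  expect_lt(abs(nm$lambda_norm - 1), 0.1)
  # ring lattice: strong clustering relative to degree-preserving nulls
  n <- 50
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in 1:2) {
      j <- ((i - 1 + s) %% n) + 1
      ring[i, j] <- ring[j, i] <- 1
    }
  }
  rl <- normalized_metrics(binary_graph(ring), n_null = 10, seed = 6)
  expect_gt(rl$gamma, 2)
})

test_that("density thresholding keeps top weights and respects ties", {
  set.seed(105)
  n <- 20
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- NA
  g <- threshold_at_density(w, 0.3)
  expect_equal(g$l, round(0.3 * n * (n - 1) / 2))
  # kept edges are exactly the strongest ones when weights are distinct
  ut <- which(upper.tri(w))
  kept <- which(g$a & upper.tri(g$a))
  expect_setequal(kept, ut[order(w[ut], decreasing = TRUE)[seq_len(g$l)]])
  # distinct weights: invariant to node order
  g2 <- threshold_at_density(w, 0.3, node_order = sample(n))
  expect_identical(g$a, g2$a)
  # unreachable density on a masked matrix errors
  w2 <- w; w2[upper.tri(w2)][1:150] <- NA; w2[lower.tri(w2)] <- t(w2)[lower.tri(w2)]
  expect_error(threshold_at_density(w2, 0.5), "unreachable")
})

test_that("metric sweep handles no-tie invariance and tie saturation", {
  set.seed(106)
  n <- 24
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- NA
  sw <- metric_sweep(w, densities = c(0.2, 0.4), node_shuffles = 4, seed = 7)
  # distinct weights: zero variance over shuffles -> CI collapses to mean
  expect_equal(sw$mcc_lo, sw$mcc, tolerance = 1e-12)
  expect_equal(sw$cpl_hi, sw$cpl, tolerance = 1e-12)
  expect_equal(sw$density, c(0.2, 0.4), tolerance = 0.01)
  # all-equal weights at density 0.5: realized density on target,
  # metrics near Erdos-Renyi expectations
  w1 <- matrix(1, n, n); diag(w1) <- NA
  sw1 <- metric_sweep(w1, densities = 0.5, node_shuffles = 12, seed = 8)
  expect_equal(sw1$density, 0.5, tolerance = 0.01)
  expect_equal(sw1$mcc, 0.5, tolerance = 0.08)       # ER: C ~ p
  expect_equal(sw1$transitivity, 0.5, tolerance = 0.08)
  expect_error(metric_sweep(w, densities = 0.7), "densities")
})

test_that("modality metric curves converge with increasing density", {
  ds <- tiny_ds()
  fpt <- fpt_chain(group_average(ds$stack))
  wd <- fpt$values; wd[!fpt$defined] <- NA
  wc <- ds$modalities$ccep$values; wc[!ds$modalities$ccep$defined] <- NA
  wr <- ds$modalities$rsfmri$values; wr[!ds$modalities$rsfmri$defined] <- NA
  dens <- c(0.1, 0.6)
  curves <- lapply(list(wd, wc, wr), function(w)
    metric_sweep(w, densities = dens, node_shuffles = 2, seed = 9))
  spread <- function(d_ix, f) {
    vals <- vapply(curves, function(cv) cv[[f]][d_ix], numeric(1))
    diff(range(vals))
  }
  for (f in c("mcc", "efficiency", "transitivity")) {
    expect_lt(spread(2, f), spread(1, f) + 1e-9)
  }
})
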