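#' Construct a binary undirected graph
#'
#' @param adjacency Logical or 0/1 numeric N x N matrix; symmetrized by OR,
#'   diagonal stripped.
#' @return A `binary_graph`: list with `a` (logical adjacency), `n` nodes,
#'   `l` undirected links.
#' @export
binary_graph <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  a <- (a != 0) & !is.na(a)
  a <- a | t(a)
  diag(a) <- FALSE
  structure(list(a = a, n = nrow(a), l = sum(a) / 2), class = "binary_graph")
}

# All-pairs shortest path lengths by level-synchronous BFS on the adjacency
# matrix (matrix products over the boolean semiring). Inf for unreachable.
shortest_paths_binary <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(TRUE, n)
  frontier <- diag(TRUE, n)
  step <- 0L
  am <- a * 1
  while (any(frontier) && step < n) {
    step <- step + 1L
    nxt <- (frontier %*% am) > 0
    frontier <- nxt & !reach
    d[frontier] <- step
    reach <- reach | frontier
  }
  d
}

#' Node-level binary network metrics
#'
#' Shortest path lengths (BFS), triangle counts, clustering coefficients
#' (0 by convention for degree < 2), per-node average distance and nodal
#' efficiency. Unreachable pairs contribute `Inf` to the average distance
#' and 0 to efficiency.
#'
#' @param g A `binary_graph`.
#' @return A list with `degree`, `triangles`, `clustering`, `distance`
#'   (N x N), `avg_distance` (L_i), `efficiency` (E_i).
#' @export
node_metrics <- function(g) {
  a <- g$a
  n <- g$n
  k <- rowSums(a)
  am <- a * 1
  t_i <- diag(am %*% am %*% am) / 2
  ci <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  d <- shortest_paths_binary(a)
  off <- d; diag(off) <- NA
  L_i <- rowMeans(off, na.rm = TRUE)
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  diag(inv) <- NA
  E_i <- rowMeans(inv, na.rm = TRUE)
  list(degree = k, triangles = t_i, clustering = ci, distance = d,
       avg_distance = L_i, efficiency = E_i)
}

#' Global binary network metrics
#'
#' Mean clustering coefficient, characteristic path length, global
#' efficiency, modularity of a given partition (Newman convention),
#' transitivity, degree assortativity over the edge set, and density
#' l / (n(n-1)/2).
#'
#' @param g A `binary_graph`.
#' @param partition Optional node-module labels for modularity Q.
#' @param disconnected `"reachable"` computes CPL over reachable pairs and
#'   reports the disconnected-pair fraction; `"inf"` propagates `Inf`.
#' @return A `graph_metrics` list: `mcc`, `cpl`, `efficiency`, `q`,
#'   `transitivity`, `assortativity`, `density`, `disconnected_fraction`,
#'   `n`, `l`.
#' @export
graph_metrics <- function(g, partition = NULL,
                          disconnected = c("reachable", "inf")) {
  disconnected <- match.arg(disconnected)
  nm <- node_metrics(g)
  a <- g$a; n <- g$n; k <- nm$degree
  off <- nm$distance; diag(off) <- NA
  disc_frac <- mean(!is.finite(off), na.rm = TRUE)
  if (disconnected == "reachable") {
    fin <- off; fin[!is.finite(fin)] <- NA
    L_i <- rowMeans(fin, na.rm = TRUE)
    cpl <- mean(L_i, na.rm = TRUE)
  } else {
    cpl <- mean(nm$avg_distance)
  }
  mcc <- mean(nm$clustering)
  eff <- mean(nm$efficiency)
  denomT <- sum(k * (k - 1))
  trans <- if (denomT > 0) sum(2 * nm$triangles) / denomT else 0
  q <- if (is.null(partition)) NA_real_ else modularity_q(a, partition)
  r <- assortativity_binary(a, k)
  structure(list(mcc = mcc, cpl = cpl, efficiency = eff, q = q,
                 transitivity = trans, assortativity = r,
                 density = g$l / (n * (n - 1) / 2),
                 disconnected_fraction = disc_frac, n = n, l = g$l),
            class = "graph_metrics")
}

# Newman modularity of a fixed partition; normalizer is the total degree
# sum (2 x undirected links), the Brain Connectivity Toolbox convention.
modularity_q <- function(a, partition) {
  l2 <- sum(a)           # = 2 * undirected links
  if (l2 == 0) return(NA_real_)
  k <- rowSums(a)
  same <- outer(partition, partition, "==")
  sum(((a * 1) - outer(k, k) / l2) * same) / l2
}

# Degree assortativity over the undirected edge set.
assortativity_binary <- function(a, k = rowSums(a)) {
  e <- which(a & upper.tri(a), arr.ind = TRUE)
  if (nrow(e) < 2L) return(NA_real_)
  ki <- k[e[, 1]]; kj <- k[e[, 2]]
  num <- mean(ki * kj) - mean((ki + kj) / 2)^2
  den <- mean((ki^2 + kj^2) / 2) - mean((ki + kj) / 2)^2
  if (den == 0) return(NA_real_)
  num / den
}

#' Null-normalized clustering, path length, and small-worldness
#'
#' Compares the graph's MCC and CPL with the means over an ensemble of null
#' networks of the same statistical makeup: degree-preserving edge
#' rewiring (default, 10 swaps per edge) or Erdos-Renyi graphs with the
#' same node and edge counts. Small-worldness is the exact ratio
#' `gamma / lambda_norm`.
#'
#' @param g A `binary_graph`.
#' @param null_model `"degree_preserving"` or `"erdos_renyi"`.
#' @param n_null Ensemble size (default 20).
#' @param swaps_per_edge Rewiring intensity (default 10).
#' @param seed Integer seed.
#' @return List with `gamma`, `lambda_norm`, `small_worldness`,
#'   `mcc_null_mean`, `cpl_null_mean`, `n_null`.
#' @export
normalized_metrics <- function(g, null_model = c("degree_preserving", "erdos_renyi"),
                               n_null = 20, swaps_per_edge = 10, seed = 1L) {
  null_model <- match.arg(null_model)
  base <- graph_metrics(g)
  nulls <- local_rng(seed, {
    lapply(seq_len(n_null), function(i) {
      an <- null_adjacency(g, null_model, swaps_per_edge)
      graph_metrics(binary_graph(an))
    })
  })
  mcc_null <- mean(vapply(nulls, `[[`, numeric(1), "mcc"))
  cpl_null <- mean(vapply(nulls, `[[`, numeric(1), "cpl"))
  gamma <- base$mcc / mcc_null
  lambda_norm <- base$cpl / cpl_null
  list(gamma = gamma, lambda_norm = lambda_norm,
       small_worldness = gamma / lambda_norm,
       mcc_null_mean = mcc_null, cpl_null_mean = cpl_null, n_null = n_null)
}

null_adjacency <- function(g, null_model, swaps_per_edge) {
  if (null_model == "erdos_renyi") {
    gr <- igraph::sample_gnm(g$n, g$l)
    return(igraph::as_adjacency_matrix(gr, sparse = FALSE) > 0)
  }
  gr <- igraph::graph_from_adjacency_matrix(g$a * 1, mode = "undirected")
  rw <- tryCatch(
    igraph::rewire(gr, igraph::keeping_degseq(niter = max(1, swaps_per_edge * g$l))),
    error = function(e) NULL)
  if (is.null(rw)) {
    warning("degree-preserving rewiring failed; using original graph as null")
    rw <- gr
  }
  igraph::as_adjacency_matrix(rw, sparse = FALSE) > 0
}

#' Binarize a weight matrix at a target edge density
#'
#' Keeps the top-weight edges (upper triangle) until the target density is
#' reached; ties are resolved by a supplied node order, mimicking the
#' order-based treatment of equal edge weights. Missing entries are treated
#' as non-connections.
#'
#' @param w Symmetric numeric matrix of edge weights (NAs = missing).
#' @param density Target binary density in (0, 1].
#' @param node_order Permutation of 1..N used to break ties.
#' @return A `binary_graph`.
#' @export
threshold_at_density <- function(w, density, node_order = seq_len(nrow(w))) {
  n <- nrow(w)
  p <- node_order
  wp <- w[p, p]
  iut <- which(upper.tri(wp), arr.ind = TRUE)
  ut <- which(upper.tri(wp))
  vals <- wp[ut]
  vals[is.na(vals)] <- -Inf
  n_edges <- round(density * n * (n - 1) / 2)
  n_avail <- sum(is.finite(vals))
  if (n_edges > n_avail) {
    stop(sprintf("density %.3f unreachable: only %d defined entries", density, n_avail))
  }
  # deterministic hash of the permuted coordinates: equal weights are kept
  # or dropped in an order that varies with the node shuffle, so averaging
  # over shuffles treats tied edges exchangeably
  tie_key <- (sin(iut[, 1] * 12.9898 + iut[, 2] * 78.233 +
                  p[iut[, 1]] * 37.719 + p[iut[, 2]] * 7.151) * 43758.5453) %% 1
  keep <- order(-vals, tie_key)[seq_len(n_edges)]
  a <- matrix(FALSE, n, n)
  a[ut[keep]] <- TRUE
  a <- a | t(a)
  inv <- order(p)
  binary_graph(a[inv, inv])
}

#' Metric sweep over binary network densities
#'
#' For each target density, thresholds the weight matrix to that density,
#' binarizes, and computes the global metric suite; node order is
#' randomized across shuffles to account for arbitrary ordering among tied
#' edge weights, and the mean metric over shuffles is reported with a
#' percentile bootstrap CI of that mean.
#'
#' @param w Symmetric weight matrix (NAs = missing, treated as
#'   non-connections).
#' @param densities Numeric grid in (0, 0.6] (default 0.05 to 0.60 by 0.05).
#' @param node_shuffles Number of random node orders (default 1000).
#' @param partition Optional module labels for Q.
#' @param null Include null-normalized metrics (`gamma`, `lambda_norm`,
#'   `small_worldness`) via [normalized_metrics()]; slower.
#' @param n_null Null ensemble size when `null = TRUE`.
#' @param boot_iters Bootstrap iterations for the CI of the shuffle mean.
#' @param seed Integer seed.
#' @return Data frame: one row per density with mean metrics over shuffles
#'   and `*_lo`, `*_hi` CI bounds.
#' @export
metric_sweep <- function(w, densities = seq(0.05, 0.60, by = 0.05),
                         node_shuffles = 1000, partition = NULL,
                         null = FALSE, n_null = 5, boot_iters = 500,
                         seed = 1L) {
  if (any(densities <= 0 | densities > 0.6)) {
    stop("densities must lie in (0, 0.6]")
  }
  n <- nrow(w)
  metric_names <- c("mcc", "cpl", "efficiency", "q", "transitivity",
                    "assortativity", "density")
  if (null) metric_names <- c(metric_names, "gamma", "lambda_norm",
                              "small_worldness")
  local_rng(seed, {
    orders <- replicate(node_shuffles, sample.int(n), simplify = FALSE)
    rows <- lapply(densities, function(dens) {
      per <- vapply(orders, function(p) {
        g <- threshold_at_density(w, dens, p)
        gm <- graph_metrics(g, partition = partition)
        out <- unlist(gm[c("mcc", "cpl", "efficiency", "q", "transitivity",
                           "assortativity", "density")])
        if (null) {
          nm <- normalized_metrics(g, n_null = n_null,
                                   seed = sample.int(.Machine$integer.max, 1))
          out <- c(out, gamma = nm$gamma, lambda_norm = nm$lambda_norm,
                   small_worldness = nm$small_worldness)
        }
        out
      }, numeric(length(metric_names)))
      per <- t(per)  # shuffles x metrics
      mu <- colMeans(per, na.rm = TRUE)
      ci <- apply(per, 2, function(col) {
        col <- col[is.finite(col)]
        if (!length(col)) return(c(NA_real_, NA_real_))
        if (length(col) == 1L) return(c(col, col))
        bm <- vapply(seq_len(boot_iters), function(i)
          mean(col[sample.int(length(col), replace = TRUE)]), numeric(1))
        stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      })
      stats::setNames(
        data.frame(target_density = dens, t(mu), t(ci[1, ]), t(ci[2, ])),
        c("target_density", metric_names,
          paste0(metric_names, "_lo"), paste0(metric_names, "_hi")))
    })
    do.call(rbind, rows)
  })
}
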