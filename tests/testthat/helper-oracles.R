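# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths (and igraph,
# where the implementation uses igraph) so agreement is a real check.

# Brute-force step-up BH adjustment.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down, cap at 1
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Floyd-Warshall all-pairs shortest path lengths on an adjacency matrix.
dist_brute <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Shortest-path counts sigma[s, t] by dynamic programming over distance.
sigma_brute <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (v in which(d[s, ] == dist)) {
        pred <- which(adj[, v] == 1 & d[s, ] == dist - 1)
        sigma[s, v] <- sum(sigma[s, pred])
      }
    }
  }
  sigma
}

# Normalised betweenness centrality by exhaustive shortest-path counting.
betweenness_brute <- function(adj) {
  n <- nrow(adj)
  d <- dist_brute(adj)
  sigma <- sigma_brute(adj, d)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# One-sided (greater) hypergeometric p by explicit enumeration of all
# overlap counts at least as large as k.
hyper_brute <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Random connected simple graph on n nodes as an igraph with named nodes.
random_connected_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
    }
  })
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Tiny wide abundance tibble from a matrix.
abundance_from_matrix <- function(m, proteins = NULL, samples = NULL) {
  rownames(m) <- proteins %||% sprintf("P%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  out <- tibble::tibble(protein = rownames(m))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Path graph a-b-c used by several hand-checkable examples.
path_abc <- function() {
  igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                              directed = FALSE)
}
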