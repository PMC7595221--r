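# Network statistics of a protein set: observed values, permutation nulls
# and empirical P values for mean degree, mean shortest path, induced-LCC
# size and mean betweenness; plus hub/bottleneck classification.

#' Induce a subgraph and keep its largest connected component
#'
#' Induces the subgraph on `ids` intersected with the network's nodes and
#' returns the largest connected component. A size tie is broken
#' deterministically toward the component containing the lexicographically
#' smallest node id.
#'
#' @param net igraph network.
#' @param ids character vector of node ids.
#' @return igraph subgraph; attributes `n_absent` (requested ids not in the
#'   network) and `n_outside_lcc` (present but dropped with smaller
#'   components).
#' @export
induce_lcc_subgraph <- function(net, ids) {
  present <- intersect(ids, igraph::V(net)$name)
  if (length(present) == 0) abort("none of the requested ids are in the network")
  sub <- igraph::induced_subgraph(net, present)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_node <- vapply(best, function(b) {
      min(igraph::V(sub)$name[comp$membership == b])
    }, character(1))
    best <- best[order(first_node)[1]]
  }
  keep <- igraph::V(sub)$name[comp$membership == best]
  out <- igraph::induced_subgraph(sub, keep)
  attr(out, "n_absent") <- length(ids) - length(present)
  attr(out, "n_outside_lcc") <- length(present) - length(keep)
  out
}

# Precompute per-node degree, normalised betweenness, the all-pairs
# distance matrix, and an adjacency index list for fast induced-LCC sizes.
network_stat_cache <- function(net) {
  if (!igraph::is_connected(net)) abort("network must be connected")
  nodes <- igraph::V(net)$name
  list(
    nodes = nodes,
    deg = stats::setNames(igraph::degree(net), nodes),
    btw = stats::setNames(igraph::betweenness(net, normalized = TRUE), nodes),
    dist = igraph::distances(net),
    adj = lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  )
}

# Size of the largest connected component of the subgraph induced on the
# node indices `idx`, via BFS over the cached adjacency lists.
lcc_size_in_set <- function(cache, idx) {
  inset <- integer(length(cache$nodes))
  inset[idx] <- seq_along(idx)
  visited <- logical(length(idx))
  best <- 0L
  for (s in seq_along(idx)) {
    if (visited[s]) next
    size <- 0L
    queue <- s
    visited[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      nb <- inset[cache$adj[[idx[v]]]]
      nb <- nb[nb > 0]
      nb <- nb[!visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best
}

set_stats_cached <- function(cache, idx) {
  dsub <- cache$dist[idx, idx, drop = FALSE]
  c(mean_degree = mean(cache$deg[idx]),
    mean_shortest_path = mean(dsub[row(dsub) != col(dsub)]),
    lcc_size = as.numeric(lcc_size_in_set(cache, idx)),
    mean_betweenness = mean(cache$btw[idx]))
}

#' Four network statistics of a node set
#'
#' Degree and normalised betweenness are computed on the whole network;
#' shortest paths run through the whole network and are averaged over
#' ordered pairs within the set; the largest-connected-component size is
#' computed on the subgraph induced on the set alone.
#'
#' @param net connected igraph network.
#' @param nodes character vector of node ids (subset of the network,
#'   length >= 2).
#' @return one-row tibble: set_size, mean_degree, mean_shortest_path,
#'   lcc_size, mean_betweenness.
#' @export
set_statistics <- function(net, nodes) {
  missing <- setdiff(nodes, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(paste0("node set not contained in the network; missing: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (length(nodes) < 2) abort("node set must have >= 2 nodes")
  cache <- network_stat_cache(net)
  idx <- match(nodes, cache$nodes)
  as_tibble(as.list(c(set_size = length(nodes), set_stats_cached(cache, idx))))
}

#' Permutation null distributions of the four set statistics
#'
#' Draws `n_samples` node sets of size `set_size` uniformly without
#' replacement from the network's nodes and computes all four statistics on
#' each (the same sampled sets are used for every statistic).
#'
#' @param net connected igraph network.
#' @param set_size size of each sampled node set.
#' @param n_samples number of permutation samples (study default 10000).
#' @param seed integer seed; identical seeds give identical nulls.
#' @return tibble with one row per sample and columns mean_degree,
#'   mean_shortest_path, lcc_size, mean_betweenness; the cache is attached
#'   as attribute `cache` for reuse.
#' @export
permutation_null <- function(net, set_size, n_samples = 10000, seed = 1L) {
  cache <- network_stat_cache(net)
  n <- length(cache$nodes)
  if (set_size > n) abort("set_size exceeds the number of network nodes")
  stats_mat <- withr::with_seed(as.integer(seed), {
    t(vapply(seq_len(n_samples), function(i) {
      set_stats_cached(cache, sample.int(n, set_size))
    }, numeric(4)))
  })
  out <- as_tibble(stats_mat)
  attr(out, "cache") <- cache
  attr(out, "set_size") <- set_size
  attr(out, "seed") <- as.integer(seed)
  out
}

#' One-sided empirical P value against a permutation null
#'
#' `P = (1 + #{null as or more extreme}) / (1 + n)` by default (add-one,
#' never exactly zero); `add_one = FALSE` gives the raw proportion. Null
#' values equal to the observed statistic count as extreme.
#'
#' @param null numeric vector of permuted statistic values.
#' @param observed observed statistic.
#' @param tail `"upper"` or `"lower"`.
#' @param add_one use the add-one (bias-corrected) estimator.
#' @return empirical P in (0, 1].
#' @export
empirical_pvalue <- function(null, observed, tail = c("upper", "lower"),
                             add_one = TRUE) {
  tail <- match.arg(tail)
  if (length(null) == 0) abort("null distribution is empty")
  extreme <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  if (add_one) (1 + extreme) / (1 + length(null)) else extreme / length(null)
}

# Tail direction per statistic, fixed a priori: enrichment of degree,
# betweenness and connectedness shows up in the upper tail; closeness of
# the set shows up as a *small* mean shortest path, hence the lower tail.
stat_tails <- c(mean_degree = "upper", mean_shortest_path = "lower",
                lcc_size = "upper", mean_betweenness = "upper")

#' Permutation significance of a node set's network statistics
#'
#' Observed statistics plus one-sided empirical P values against the
#' permutation null (upper tail for mean degree, LCC size and mean
#' betweenness; lower tail for mean shortest path).
#'
#' @inheritParams set_statistics
#' @inheritParams permutation_null
#' @param add_one see [empirical_pvalue()].
#' @return tibble: statistic, observed, tail, p; the null tibble is
#'   attached as attribute `null`.
#' @export
network_significance <- function(net, nodes, n_samples = 10000, seed = 1L,
                                 add_one = TRUE) {
  observed <- set_statistics(net, nodes)
  null <- permutation_null(net, length(nodes), n_samples, seed)
  out <- purrr::map_dfr(names(stat_tails), function(stat) {
    obs_value <- observed[[stat]]
    tibble(statistic = stat,
           observed = obs_value,
           tail = stat_tails[[stat]],
           p = empirical_pvalue(null[[stat]], obs_value,
                                stat_tails[[stat]], add_one))
  })
  attr(out, "null") <- null
  out
}

#' Classify hubs and bottlenecks
#'
#' Hubs have degree strictly above the `percentile` quantile of all nodes;
#' bottlenecks have betweenness strictly above its `percentile` quantile
#' (linear-interpolation quantiles over the analysis network's nodes).
#'
#' @param net connected igraph network.
#' @param percentile quantile threshold (default 0.9, the 90th percentile).
#' @return tibble per node: node, degree, betweenness, degree_percentile,
#'   betweenness_percentile, class in {hub-bottleneck, nonhub-bottleneck,
#'   hub-nonbottleneck, neither}.
#' @export
classify_hub_bottleneck <- function(net, percentile = 0.9) {
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, normalized = TRUE)
  deg_thr <- stats::quantile(deg, percentile, names = FALSE)
  btw_thr <- stats::quantile(btw, percentile, names = FALSE)
  hub <- deg > deg_thr
  bottleneck <- btw > btw_thr
  ecdf_deg <- stats::ecdf(deg)
  ecdf_btw <- stats::ecdf(btw)
  tibble(
    node = nodes, degree = as.numeric(deg), betweenness = as.numeric(btw),
    degree_percentile = ecdf_deg(deg), betweenness_percentile = ecdf_btw(btw),
    class = dplyr::case_when(
      hub & bottleneck ~ "hub-bottleneck",
      !hub & bottleneck ~ "nonhub-bottleneck",
      hub & !bottleneck ~ "hub-nonbottleneck",
      TRUE ~ "neither"
    )
  )
}
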