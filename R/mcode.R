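# MCODE dense-module detection (Bader & Hogue): k-core based vertex
# weighting, greedy seed expansion with a vertex weight percentage
# threshold, haircut post-processing and density x size scoring.

#' Subgraph of a query set plus its direct neighbours
#'
#' Induces the subgraph on `ids` and every direct neighbour of `ids`, then
#' keeps the largest connected component.
#'
#' @param net igraph network.
#' @param ids character vector of query node ids.
#' @return igraph subgraph; attributes `n_query` (query nodes retained),
#'   `n_neighbour` (neighbour-only nodes retained) and `n_absent` (query
#'   ids missing from the network).
#' @export
neighbourhood_subgraph <- function(net, ids) {
  present <- intersect(ids, igraph::V(net)$name)
  if (length(present) == 0) abort("none of the requested ids are in the network")
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(net, present),
    function(v) igraph::V(net)$name[as.integer(v)]
  )))
  keep <- union(present, nb)
  out <- induce_lcc_subgraph(net, keep)
  retained <- igraph::V(out)$name
  attr(out, "n_query") <- length(intersect(retained, present))
  attr(out, "n_neighbour") <- length(setdiff(retained, present))
  attr(out, "n_absent") <- length(ids) - length(present)
  out
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' The weight of a vertex is the order of the highest k-core of its closed
#' neighbourhood multiplied by the density of that core's subgraph;
#' isolated vertices weigh 0.
#'
#' @param net simple igraph network.
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  w <- vapply(seq_along(nodes), function(i) {
    nb <- c(i, as.integer(adj[[i]]))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(net, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) return(0)
    core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
    kmax * graph_density(core_sub)
  }, numeric(1))
  stats::setNames(w, nodes)
}

# Iteratively strip degree-1 vertices from a module subgraph (haircut).
haircut_nodes <- function(net, nodes) {
  repeat {
    if (length(nodes) < 2) return(nodes)
    sub <- igraph::induced_subgraph(net, nodes)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg <= 1]
    if (length(drop) == 0 || length(drop) == length(nodes)) return(nodes)
    nodes <- setdiff(nodes, drop)
  }
}

#' MCODE dense-module detection
#'
#' Greedy seed expansion from the highest-weight unassigned vertex:
#' neighbours are included (breadth-first, to `max_depth`) when their
#' weight exceeds `seed_weight * (1 - vwp)` and they are not yet part of
#' another module. Modules are haircut (degree-1 vertices removed) when
#' `haircut` is on, must contain a k-core of order `kcore`, and are scored
#' as density x size. Vertices with degree below `degree_cutoff` never
#' seed. Ties on seed weight break toward the lexicographically smallest
#' node id. Defaults are the canonical published MCODE parameters.
#'
#' @param net simple igraph network.
#' @param vwp vertex weight percentage in [0, 1).
#' @param degree_cutoff minimum degree for seeding (default 2).
#' @param kcore minimum core order a module must contain (default 2).
#' @param haircut remove degree-1 module vertices (default TRUE).
#' @param max_depth breadth limit of the expansion (default 100).
#' @param score_cutoff if set, only modules with score strictly greater
#'   are reported (the study reported modules with score > 10).
#' @return tibble of class `mcode_result`, sorted by score descending:
#'   module, score, size, seed_node, nodes (list column).
#' @export
mcode <- function(net, vwp = 0.2, degree_cutoff = 2, kcore = 2,
                  haircut = TRUE, max_depth = 100, score_cutoff = NULL) {
  if (vwp < 0 || vwp >= 1) abort("vwp must be in [0, 1)")
  nodes <- igraph::V(net)$name
  if (length(nodes) == 0 || igraph::ecount(net) == 0) {
    return(structure(tibble(module = integer(0), score = numeric(0),
                            size = integer(0), seed_node = character(0),
                            nodes = list()),
                     class = c("mcode_result", class(tibble()))))
  }
  w <- vertex_weights(net)
  deg <- igraph::degree(net)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  order_idx <- order(-w, nodes)  # weight desc, lexicographic tie-break
  used <- logical(length(nodes))
  modules <- list()
  for (seed in order_idx) {
    if (used[seed] || deg[seed] < degree_cutoff) next
    threshold <- w[seed] * (1 - vwp)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!used[u] && w[u] > threshold) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    mod_nodes <- nodes[members]
    if (haircut) mod_nodes <- haircut_nodes(net, mod_nodes)
    if (length(mod_nodes) < 2) next
    sub <- igraph::induced_subgraph(net, mod_nodes)
    if (max(igraph::coreness(sub)) < kcore) next
    modules[[length(modules) + 1]] <- tibble(
      score = graph_density(sub) * length(mod_nodes),
      size = length(mod_nodes),
      seed_node = nodes[seed],
      nodes = list(sort(mod_nodes))
    )
  }
  out <- bind_rows(modules)
  if (nrow(out) == 0) {
    out <- tibble(score = numeric(0), size = integer(0),
                  seed_node = character(0), nodes = list())
  }
  out <- out |> arrange(desc(.data$score), .data$seed_node)
  if (!is.null(score_cutoff)) out <- out[out$score > score_cutoff, ]
  out <- bind_cols(tibble(module = seq_len(nrow(out))), out)
  structure(out, class = c("mcode_result", class(tibble())))
}

#' Fraction of a module in a query set
#'
#' @param module_nodes character vector of module node ids (or a one-row
#'   slice of an [mcode()] result's `nodes` entry).
#' @param query character vector of query ids (e.g. significantly altered
#'   proteins).
#' @return |module intersect query| / |module|.
#' @export
module_query_fraction <- function(module_nodes, query) {
  if (is.list(module_nodes)) module_nodes <- module_nodes[[1]]
  if (length(module_nodes) == 0) abort("module is empty")
  length(intersect(module_nodes, query)) / length(module_nodes)
}
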