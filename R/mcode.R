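# MCODE-style molecular-complex detection. The variant is pinned:
# closed-neighborhood k-core vertex weighting, greedy seeded growth with a
# node-score cutoff, 2-core post-filter with haircut, module score =
# density x node count, single membership (visited-node rule), and
# lexicographic tie-breaks so runs are reproducible under any input
# ordering.

graph_density <- function(n, e) {
  if (n < 2) return(0)
  2 * e / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' For each node v with degree >= `degree_cutoff`, take the closed
#' neighborhood N[v], find its highest k-core (the maximal subgraph where
#' every node has within-subgraph degree >= k, for the largest feasible
#' k), and set `weight(v) = k_max * density(core)`. Nodes below the degree
#' cutoff get weight 0.
#'
#' @param net an igraph network.
#' @param degree_cutoff minimum degree to receive a weight (default 2).
#' @return named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2) {
  vs <- igraph::V(net)$name
  deg <- igraph::degree(net)
  w <- stats::setNames(numeric(length(vs)), vs)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (i in seq_along(vs)) {
    if (deg[i] < degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, nb)
    core <- igraph::coreness(sub)
    k_max <- max(core)
    if (k_max == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(core == k_max))
    w[i] <- k_max * graph_density(igraph::vcount(core_sub),
                                  igraph::ecount(core_sub))
  }
  w
}

#' Grow candidate modules from high-weight seeds
#'
#' Seeds are unvisited positive-weight nodes in descending weight order
#' (lexicographic symbol tie-break). From each seed, breadth-first
#' expansion admits an unvisited neighbor u iff
#' `weight(u) >= (1 - node_score_cutoff) * weight(seed)` and the BFS depth
#' does not exceed `max_depth`. Admitted nodes are marked visited and
#' belong to exactly one candidate.
#'
#' @param net an igraph network.
#' @param weights vector from [mcode_vertex_weights()].
#' @param node_score_cutoff admission slack relative to the seed weight
#'   (default 0.2).
#' @param max_depth BFS depth limit (default 100).
#' @return list of candidates, each a list with `nodes` (sorted) and
#'   `seed`.
#' @export
mcode_grow <- function(net, weights, node_score_cutoff = 0.2,
                       max_depth = 100) {
  vs <- igraph::V(net)$name
  if (length(vs) == 0) return(list())
  weights <- weights[vs]
  order_idx <- order(-weights, vs)
  visited <- stats::setNames(logical(length(vs)), vs)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, function(a) vs[as.integer(a)])
  names(adj) <- vs
  out <- list()
  for (i in order_idx) {
    seed <- vs[i]
    if (visited[seed] || weights[seed] <= 0) next
    thresh <- (1 - node_score_cutoff) * weights[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- character()
      for (v in frontier) {
        for (u in sort(adj[[v]])) {
          if (!visited[u] && weights[u] >= thresh) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    out[[length(out) + 1]] <- list(nodes = sort(members), seed = seed)
  }
  out
}

#' Post-process candidate modules (k-core filter, haircut, rescore)
#'
#' Discards candidates whose induced subgraph has no `k_core`-core;
#' `haircut` then removes nodes with within-module degree 1 (single pass);
#' density and score (= density x node count) are recomputed on the final
#' node set; modules with fewer than 2 nodes are dropped. `fluff` is
#' accepted for interface completeness but not implemented (the pinned
#' variant runs without it).
#'
#' @param candidates list from [mcode_grow()].
#' @param net the network the candidates came from.
#' @param k_core required core level (default 2).
#' @param haircut remove within-module degree-1 nodes (default TRUE).
#' @param fluff must be FALSE.
#' @return list of modules (`nodes`, `seed`, `density`, `score`), sorted
#'   by score descending with seed tie-break.
#' @export
mcode_postprocess <- function(candidates, net, k_core = 2, haircut = TRUE,
                              fluff = FALSE) {
  if (isTRUE(fluff)) stop("fluff expansion is not implemented")
  out <- list()
  for (cand in candidates) {
    if (length(cand$nodes) < 2) next
    sub <- igraph::induced_subgraph(net, cand$nodes)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    nodes <- igraph::V(sub)$name
    if (haircut) {
      keep <- igraph::degree(sub) > 1
      nodes <- nodes[keep]
      if (length(nodes) < 2) next
      sub <- igraph::induced_subgraph(net, nodes)
    }
    n <- igraph::vcount(sub)
    dens <- graph_density(n, igraph::ecount(sub))
    out[[length(out) + 1]] <- list(nodes = sort(nodes), seed = cand$seed,
                                   density = dens, score = dens * n)
  }
  if (length(out) > 1) {
    ord <- order(-vapply(out, `[[`, 0, "score"),
                 vapply(out, `[[`, "", "seed"))
    out <- out[ord]
  }
  out
}

#' Filter modules by score
#'
#' @param modules list from [mcode_postprocess()].
#' @param min_score strict lower bound on `density * size` (default 5).
#' @return filtered list, order preserved.
#' @export
filter_modules <- function(modules, min_score = 5) {
  Filter(function(m) m$score > min_score, modules)
}

#' Detect dense network modules (full MCODE-style pass)
#'
#' Convenience wrapper chaining [mcode_vertex_weights()], [mcode_grow()],
#' [mcode_postprocess()] and (optionally) [filter_modules()].
#'
#' @param net an igraph network.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth,haircut
#'   algorithm parameters (defaults 2, 0.2, 2, 100, TRUE — the
#'   conventional defaults).
#' @param min_score strict module-score filter; `NULL` keeps all modules.
#' @return list of modules (`nodes`, `seed`, `density`, `score`).
#' @export
find_modules <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE,
                         min_score = 5) {
  w <- mcode_vertex_weights(net, degree_cutoff)
  cand <- mcode_grow(net, w, node_score_cutoff, max_depth)
  mods <- mcode_postprocess(cand, net, k_core = k_core, haircut = haircut)
  if (!is.null(min_score)) mods <- filter_modules(mods, min_score)
  mods
}
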