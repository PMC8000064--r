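#' Build a confidence-filtered interaction network
#'
#' Keeps edges with confidence strictly greater than `min_confidence`
#' whose endpoints both lie in `restrict_to` (typically the DEG set),
#' deduplicates, and returns a simple undirected igraph with a
#' `confidence` edge attribute. Genes listed in `keep_isolated` are
#' retained as isolated vertices even if all their edges are filtered out.
#'
#' @param edges data.frame with `node_a`, `node_b`, `confidence` (unit
#'   scale), e.g. from [read_edge_list()] or [simulate_network()].
#' @param min_confidence strict lower bound on edge confidence
#'   (default 0.4, the conventional medium-confidence filter).
#' @param restrict_to optional character vector restricting the node set.
#' @param keep_isolated optional character vector of vertices to retain
#'   even when isolated.
#' @return an undirected simple `igraph` object.
#' @export
build_network <- function(edges, min_confidence = 0.4, restrict_to = NULL,
                          keep_isolated = NULL) {
  keep <- edges$confidence > min_confidence
  if (!is.null(restrict_to))
    keep <- keep & edges$node_a %in% restrict_to &
      edges$node_b %in% restrict_to
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) == 0)
    warning("no edge passes the filters; returning an empty network")
  g <- igraph::graph_from_data_frame(
    e[, c("node_a", "node_b", "confidence")], directed = FALSE,
    vertices = sort(unique(c(e$node_a, e$node_b, keep_isolated))))
  igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
}

#' Degree centrality (raw incident-edge counts)
#'
#' @param net an igraph network.
#' @return named numeric vector.
#' @export
degree_centrality <- function(net) {
  igraph::degree(net, loops = FALSE)
}

#' Closeness centrality with per-component scaling
#'
#' For a node v in a connected component of size `n_c`, closeness is
#' `(n_c - 1) / sum of shortest-path distances from v` when
#' `normalized = TRUE` (so it lies in (0, 1], reaching 1 only when v is
#' adjacent to every other node of its component), and
#' `1 / sum of distances` otherwise. Distances ignore edge confidences.
#' Isolated nodes get 0.
#'
#' @param net an igraph network.
#' @param normalized use the per-component `(n_c - 1)` scaling.
#' @param wf_scaling additionally multiply by the Wasserman-Faust factor
#'   `(n_c - 1)/(n - 1)` to compare across components.
#' @return named numeric vector.
#' @export
closeness_centrality <- function(net, normalized = TRUE,
                                 wf_scaling = FALSE) {
  n <- igraph::vcount(net)
  out <- stats::setNames(numeric(n), igraph::V(net)$name)
  if (n == 0) return(out)
  d <- igraph::distances(net, weights = NA)
  comp <- igraph::components(net)
  for (v in seq_len(n)) {
    members <- which(comp$membership == comp$membership[v])
    n_c <- length(members)
    if (n_c < 2) next
    tot <- sum(d[v, members])
    out[v] <- if (normalized) (n_c - 1) / tot else 1 / tot
    if (wf_scaling && n > 1) out[v] <- out[v] * (n_c - 1) / (n - 1)
  }
  out
}

#' Betweenness centrality (Brandes), optionally pair-normalized
#'
#' Unweighted shortest-path betweenness; with `normalized = TRUE` the raw
#' value is divided by `(n - 1)(n - 2) / 2`, the number of node pairs that
#' could route through a given node, so results lie in [0, 1]. Graphs with
#' fewer than 3 nodes get all zeros.
#'
#' @param net an igraph network.
#' @param normalized divide by `(n - 1)(n - 2)/2`.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  n <- igraph::vcount(net)
  if (n < 3)
    return(stats::setNames(numeric(n), igraph::V(net)$name))
  b <- igraph::betweenness(net, directed = FALSE, weights = NA)
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

#' Mean degree of a node's neighbors
#'
#' Arithmetic mean of the raw degrees of the adjacent nodes; isolated
#' nodes get 0 (flagged via the `isolated` attribute on the result).
#'
#' @param net an igraph network.
#' @return named numeric vector with attribute `isolated` (logical).
#' @export
mean_neighbor_degree <- function(net) {
  deg <- igraph::degree(net)
  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  s <- as.vector(adj %*% deg)
  out <- ifelse(deg > 0, s / deg, 0)
  names(out) <- igraph::V(net)$name
  attr(out, "isolated") <- deg == 0
  out
}

#' Hybrid centrality: degree + closeness + betweenness + mean neighbor degree
#'
#' The hub score is the plain sum of four per-node terms: degree,
#' closeness, betweenness and the mean degree of the node's neighbors.
#' Because the four terms live on different scales, the normalization
#' applied to each is explicit and stamped into the output:
#'
#' * `"default"` — raw degree + component-normalized closeness (0-1) +
#'   pair-normalized betweenness (0-1) + raw mean neighbor degree. The
#'   degree-scale terms dominate, which is what makes a double-digit hub
#'   threshold meaningful.
#' * `"all_raw"` — raw degree + `1/sum(d)` closeness + raw Brandes
#'   betweenness + raw mean neighbor degree.
#' * `"all_normalized"` — degree/(n-1) + normalized closeness + normalized
#'   betweenness + mean neighbor degree/(n-1).
#'
#' @param net an igraph network.
#' @param mode normalization mode (see above).
#' @return data.frame with columns `gene`, `degree`, `closeness`,
#'   `betweenness`, `mean_neighbor_degree`, `hcm` and an `isolated` flag;
#'   attribute `mode` records the normalization. Sorted by `hcm`
#'   descending, ties by symbol.
#' @export
hybrid_centrality <- function(net, mode = c("default", "all_raw",
                                            "all_normalized")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(net)
  deg <- degree_centrality(net)
  mnd <- mean_neighbor_degree(net)
  iso <- attr(mnd, "isolated")
  clo <- closeness_centrality(net, normalized = mode != "all_raw")
  bet <- betweenness_centrality(net, normalized = mode != "all_raw")
  deg_term <- deg
  mnd_term <- as.vector(mnd)
  if (mode == "all_normalized" && n > 1) {
    deg_term <- deg / (n - 1)
    mnd_term <- mnd_term / (n - 1)
  }
  out <- data.frame(gene = igraph::V(net)$name,
                    degree = as.vector(deg),
                    closeness = as.vector(clo),
                    betweenness = as.vector(bet),
                    mean_neighbor_degree = as.vector(mnd),
                    hcm = deg_term + as.vector(clo) + as.vector(bet) +
                      mnd_term,
                    isolated = iso,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$hcm, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Select hub genes by hybrid centrality threshold
#'
#' Keeps nodes with `hcm` strictly greater than `threshold` and annotates
#' each with its regulation direction from DEG records (sign of logFC for
#' called DEGs); genes without a DEG record get direction `"unknown"`.
#'
#' @param metrics data.frame from [hybrid_centrality()].
#' @param threshold strict lower bound on the hub score (default 12).
#' @param deg optional data.frame from [call_degs()].
#' @return subset of `metrics` with a `direction` column, sorted by `hcm`
#'   descending with symbol tie-break.
#' @export
select_hubs <- function(metrics, threshold = 12, deg = NULL) {
  hubs <- metrics[metrics$hcm > threshold, , drop = FALSE]
  if (!is.null(deg)) {
    dirs <- stats::setNames(deg$direction, deg$gene)
    d <- dirs[hubs$gene]
    missing <- is.na(d) | d == "none"
    if (any(is.na(d)))
      message(sum(is.na(d)), " hub gene(s) without a DEG record")
    hubs$direction <- ifelse(missing, "unknown", d)
  } else {
    hubs$direction <- "unknown"
  }
  hubs <- hubs[order(-hubs$hcm, hubs$gene), , drop = FALSE]
  rownames(hubs) <- NULL
  attr(hubs, "mode") <- attr(metrics, "mode")
  hubs
}
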