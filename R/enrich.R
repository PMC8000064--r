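#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` annotated genes when drawing a
#' query of size `n` from a universe of size `N` containing `K` annotated
#' members — the one-sided over-representation p-value (equivalent to a
#' one-sided Fisher exact test). With `ease = TRUE` the observed overlap
#' is reduced by one (floored at 0) before taking the tail, the
#' conservative EASE-score variant.
#'
#' @param k observed overlap.
#' @param n query size.
#' @param K annotated (set) size in the universe.
#' @param N universe size.
#' @param ease use the overlap-minus-one variant.
#' @return tail probability in [0, 1]. Vectorized over `k`, `n`, `K`.
#' @export
hypergeometric_tail <- function(k, n, K, N, ease = FALSE) {
  if (any(k < 0) || any(k > pmin(n, K)) || any(pmax(n, K) > N))
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  if (ease) k <- pmax(k - 1, 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests every set of a collection for over-representation in the query
#' via the upper-tail hypergeometric probability. The universe defaults to
#' the collection's universe extended by the query; set and query are
#' intersected with the universe before counting.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_sets] object.
#' @param universe optional explicit background symbols.
#' @param min_count minimum overlap to report (inclusive; default 2).
#' @param p_threshold strict p-value filter (default 0.05).
#' @param adjust `"none"` (default) or `"bh"` (Benjamini-Hochberg;
#'   filtering still applies to the raw p, matching raw-p reporting
#'   practice).
#' @param ease use the EASE variant of the tail (default FALSE).
#' @return data.frame with columns `set_id`, `description`,
#'   `overlap_count`, `p_value`, (`adjusted_p`,) `overlap_genes`
#'   (comma-joined), sorted by p ascending with set-id tie-break.
#'   Attributes `universe_size` and `query_size` record the margins used.
#' @export
enrich <- function(query, collection, universe = NULL, min_count = 2,
                   p_threshold = 0.05, adjust = c("none", "bh"),
                   ease = FALSE) {
  stopifnot(inherits(collection, "gene_sets"))
  adjust <- match.arg(adjust)
  query <- unique(query)
  if (length(query) == 0) stop("empty query")
  if (length(intersect(query, unlist(collection$sets))) == 0)
    stop("query shares no symbol with any set: symbol-space mismatch?")
  if (is.null(universe))
    universe <- union(collection$universe, query)
  q <- intersect(query, universe)
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(collection$sets), function(id) {
    s <- intersect(collection$sets[[id]], universe)
    ov <- sort(intersect(q, s))
    data.frame(set_id = id,
               description = collection$descriptions[[id]],
               overlap_count = length(ov),
               set_size = length(s),
               p_value = hypergeometric_tail(length(ov), n, length(s), N,
                                             ease = ease),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust == "bh")
    res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < p_threshold & res$overlap_count >= min_count, ,
             drop = FALSE]
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "universe_size") <- N
  attr(res, "query_size") <- n
  res
}

#' Tally regulation directions within enrichment overlaps
#'
#' Adds `n_up`, `n_down` and `n_unknown` columns counting the overlap
#' genes' directions from DEG records;
#' `n_up + n_down + n_unknown == overlap_count` always.
#'
#' @param result data.frame from [enrich()].
#' @param deg data.frame from [call_degs()].
#' @return the result with tally columns appended.
#' @export
tally_directions <- function(result, deg) {
  dirs <- stats::setNames(deg$direction, deg$gene)
  tallies <- t(vapply(result$overlap_genes, function(gs) {
    genes <- if (nzchar(gs)) strsplit(gs, ",", fixed = TRUE)[[1]]
             else character()
    d <- dirs[genes]
    c(n_up = sum(d == "up", na.rm = TRUE),
      n_down = sum(d == "down", na.rm = TRUE),
      n_unknown = sum(is.na(d) | d == "none"))
  }, c(n_up = 0, n_down = 0, n_unknown = 0)))
  rownames(tallies) <- NULL
  cbind(result, as.data.frame(tallies))
}
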