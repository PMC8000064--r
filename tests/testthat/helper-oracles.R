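# Independent brute-force oracles. Everything here works from a plain
# adjacency matrix with its own BFS / enumeration code, deliberately not
# touching igraph or the package's implementation paths.

oracle_adjacency <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    if (a != b) { A[a, b] <- 1L; A[b, a] <- 1L }
  }
  A
}

oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    nb <- which(A[v, ] == 1L)
    new <- nb[d[nb] == Inf]
    d[new] <- d[v] + 1
    q <- c(q, new)
  }
  d
}

# distances, shortest-path counts, and the four centrality terms
oracle_metrics <- function(edges, nodes = NULL, normalized = TRUE) {
  A <- oracle_adjacency(edges, nodes)
  n <- nrow(A)
  deg <- rowSums(A)
  D <- t(vapply(seq_len(n), function(s) oracle_bfs(A, s), numeric(n)))
  # sigma[s, u]: number of shortest s-u paths, by dynamic programming over
  # increasing distance layers
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (u in reach[order(D[s, reach])]) {
      if (u == s) next
      preds <- which(A[, u] == 1L & D[s, ] == D[s, u] - 1)
      sigma[s, u] <- sum(sigma[s, preds])
    }
  }
  betw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          betw[v] <- betw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (normalized && n > 2) betw <- betw / ((n - 1) * (n - 2) / 2)
  clo <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(is.finite(D[v, ]))
    if (length(members) < 2) next
    clo[v] <- if (normalized) (length(members) - 1) / sum(D[v, members])
              else 1 / sum(D[v, members])
  }
  mnd <- ifelse(deg > 0, as.vector(A %*% deg) / deg, 0)
  list(nodes = rownames(A), degree = unname(deg), closeness = clo,
       betweenness = betw, mean_neighbor_degree = unname(mnd))
}

# highest k-core by iterated peeling (independent of igraph::coreness)
oracle_top_kcore <- function(A) {
  best_k <- 0; best_nodes <- integer()
  for (k in seq_len(nrow(A))) {
    keep <- seq_len(nrow(A))
    repeat {
      d <- rowSums(A[keep, keep, drop = FALSE])
      drop <- keep[d < k]
      if (!length(drop)) break
      keep <- setdiff(keep, drop)
      if (!length(keep)) break
    }
    if (!length(keep)) break
    best_k <- k; best_nodes <- keep
  }
  list(k = best_k, nodes = best_nodes)
}

oracle_density <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  sum(A) / (n * (n - 1))  # sum counts both directions -> 2e
}

# hypergeometric upper tail by closed-form binomial-coefficient sums
oracle_hyper_tail <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# ... and by literal enumeration of every draw (small N only)
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# product-limit estimate by direct hand computation
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# two-group log-rank chi-square by per-event-time 2x2 tables
oracle_logrank <- function(time, event, group) {
  g1 <- levels(as.factor(group))[1]
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# small named graphs used across the suite
fixture_star <- function(n_leaves = 4) {
  data.frame(node_a = rep("C", n_leaves),
             node_b = paste0("L", seq_len(n_leaves)),
             confidence = 0.9, stringsAsFactors = FALSE)
}

fixture_triangle <- function() {
  data.frame(node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
             confidence = 0.9, stringsAsFactors = FALSE)
}

fixture_path3 <- function() {
  data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
             confidence = 0.9, stringsAsFactors = FALSE)
}

fixture_er_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("V%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
             confidence = 0.9, stringsAsFactors = FALSE)
}

fixture_clique_edges <- function(members, confidence = 0.9) {
  pairs <- utils::combn(members, 2)
  data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
             confidence = confidence, stringsAsFactors = FALSE)
}
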