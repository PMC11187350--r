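# Exhaustive shortest-path oracle, independent of igraph: plain per-source
# breadth-first search over an adjacency list. Used to cross-check every
# network metric.

oracle_adjacency <- function(nodes, from, to) {
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- union(adj[[from[i]]], to[i])
    adj[[to[i]]] <- union(adj[[to[i]]], from[i])
  }
  adj
}

oracle_bfs <- function(adj, source) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# All-pairs matrix by exhaustive per-source BFS.
oracle_all_pairs <- function(nodes, from, to) {
  adj <- oracle_adjacency(nodes, from, to)
  m <- t(vapply(nodes, function(s) oracle_bfs(adj, s),
                stats::setNames(numeric(length(nodes)), nodes)))
  dimnames(m) <- list(nodes, nodes)
  m
}

oracle_closest <- function(D, X, Y) {
  mins <- apply(D[X, Y, drop = FALSE], 2, min)
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0) NA_real_ else mean(mins)
}

oracle_internal <- function(D, A) {
  if (length(A) == 1) return(0)
  sub <- D[A, A, drop = FALSE]
  diag(sub) <- Inf
  mins <- apply(sub, 1, min)
  mins <- mins[is.finite(mins)]
  if (length(mins) == 0) NA_real_ else mean(mins)
}

oracle_separation <- function(D, A, B) {
  to_b <- apply(D[A, B, drop = FALSE], 2, min)
  to_a <- apply(D[B, A, drop = FALSE], 2, min)
  cross <- c(to_b[is.finite(to_b)], to_a[is.finite(to_a)])
  d_ab <- if (length(cross)) mean(cross) else NA_real_
  d_aa <- oracle_internal(D, A)
  d_bb <- oracle_internal(D, B)
  list(d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
       s_ab = d_ab - (d_aa + d_bb) / 2)
}

# Seeded random edge list over n nodes (may be disconnected).
random_edgelist <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes, from = pairs[keep, 1], to = pairs[keep, 2])
}

path_graph <- function(labels) {
  n <- length(labels)
  ppi_from_edges(labels[-n], labels[-1])
}
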