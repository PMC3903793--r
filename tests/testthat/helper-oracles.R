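# Independent brute-force oracles. These deliberately avoid the package's
# (and igraph's) code paths: the clustering coefficient comes from adjacency-
# matrix triple products, betweenness from explicit path enumeration.

# mean local clustering coefficient from an adjacency matrix
oracle_clustering_coefficient <- function(adj) {
  n <- nrow(adj)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      e <- e + adj[nb[a], nb[b]]
    }
    local[i] <- 2 * e / (k * (k - 1))
  }
  mean(local)
}

# all shortest paths between two nodes by breadth-limited DFS enumeration
enumerate_shortest_paths <- function(adj, from, to) {
  n <- nrow(adj)
  best <- list(len = Inf, paths = list())
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      if (length(path) < best$len) best <<- list(len = length(path), paths = list(path))
      else if (length(path) == best$len) best$paths[[length(best$paths) + 1L]] <<- path
      return()
    }
    if (length(path) >= best$len) return()
    for (nxt in which(adj[last, ] == 1)) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  best$paths
}

# exact edge betweenness by path enumeration; returns named vector "i|j", i<j
oracle_edge_betweenness <- function(adj) {
  n <- nrow(adj)
  eb <- numeric()
  key <- function(i, j) paste(min(i, j), max(i, j), sep = "|")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j] == 1 && i < j) eb[key(i, j)] <- 0
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_shortest_paths(adj, s, t)
    if (length(paths) == 0) next
    w <- 1 / length(paths)
    for (p in paths) {
      for (e in seq_len(length(p) - 1)) {
        eb[key(p[e], p[e + 1])] <- eb[key(p[e], p[e + 1])] + w
      }
    }
  }
  eb
}

# silhouette by direct double loops over a dissimilarity matrix
oracle_silhouette <- function(clusters, d) {
  ids <- unlist(clusters)
  s <- setNames(numeric(length(ids)), ids)
  for (ci in seq_along(clusters)) {
    own <- clusters[[ci]]
    for (id in own) {
      if (length(own) == 1) { s[id] <- 0; next }
      a <- mean(sapply(setdiff(own, id), function(o) d[id, o]))
      b <- Inf
      for (cj in seq_along(clusters)) {
        if (cj == ci) next
        b <- min(b, mean(sapply(clusters[[cj]], function(o) d[id, o])))
      }
      s[id] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
  }
  s
}

# adjacency matrix -> named igraph
graph_from_adj <- function(adj, names = NULL) {
  if (is.null(names)) names <- sprintf("n%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(names, names)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = NULL)
}

random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj + t(adj)
}

# adjacency matrix of graph index `mask` over n nodes (bit per upper-tri edge)
adj_from_mask <- function(n, mask) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  bits <- as.integer(intToBits(mask))[seq_along(up)]
  adj[up] <- bits
  adj + t(adj)
}
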