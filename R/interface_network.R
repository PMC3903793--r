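#' Build the interface-similarity network
#'
#' One node per interface; an edge is drawn between two interfaces when
#' their similarity reaches `edge_threshold` (default 0.75, the level
#' below which clusters are considered structurally distinct). Interfaces
#' without any qualifying partner remain as isolated nodes. Every node
#' carries a `members` attribute (initially itself) so that the same graph
#' type represents condensed supernode networks.
#'
#' @param sim a `piface_simtable`, a plain `iface1`/`iface2`/`similarity`
#'   data frame, or a symmetric similarity matrix.
#' @param edge_threshold minimum similarity for an edge.
#' @param nodes node names; defaults to the names recorded in `sim`.
#' @return an `igraph` graph with vertex attributes `name`, `members`
#'   (list of interface ids) and edge attribute `weight`.
#' @export
build_network <- function(sim, edge_threshold = 0.75, nodes = NULL) {
  if (is.matrix(sim)) {
    nms <- rownames(sim)
    idx <- which(upper.tri(sim) & sim >= edge_threshold, arr.ind = TRUE)
    tab <- data.frame(iface1 = nms[idx[, 1L]], iface2 = nms[idx[, 2L]],
                      similarity = sim[idx], stringsAsFactors = FALSE)
    if (is.null(nodes)) nodes <- nms
  } else {
    tab <- as.data.frame(sim)
    if (is.null(nodes)) nodes <- attr(sim, "interface_names")
    if (is.null(nodes)) nodes <- sort(unique(c(tab$iface1, tab$iface2)))
    tab <- tab[tab$similarity >= edge_threshold &
                 tab$iface1 != tab$iface2, , drop = FALSE]
  }
  nodes <- sort(unique(nodes))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(tab) > 0L) {
    g <- igraph::add_edges(g, rbind(match(tab$iface1, nodes),
                                    match(tab$iface2, nodes)),
                           weight = tab$similarity)
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  }
  igraph::set_vertex_attr(g, "members", value = as.list(nodes))
}

node_members <- function(g) {
  m <- igraph::vertex_attr(g, "members")
  if (is.null(m)) m <- as.list(igraph::V(g)$name)
  m
}

n_member_interfaces <- function(g) sum(lengths(node_members(g)))

#' Mean local clustering coefficient
#'
#' For each node `i` with degree `k_i >= 2`, the local coefficient is
#' `2 e_i / (k_i (k_i - 1))` where `e_i` counts edges among `i`'s
#' neighbours; nodes with degree below 2 contribute 0. The network value is
#' the mean over all nodes, in `[0, 1]` (1 for cliques).
#'
#' @param net an `igraph` graph.
#' @return numeric scalar in `[0, 1]`; 0 for an empty-edge graph.
#' @export
clustering_coefficient <- function(net) {
  n <- igraph::vcount(net)
  stopifnot(n >= 1L)
  local <- numeric(n)
  adj <- igraph::as_adj_list(net, mode = "all")
  for (i in seq_len(n)) {
    nb <- unique(as.integer(adj[[i]]))
    nb <- nb[nb != i]
    k <- length(nb)
    if (k < 2L) next
    e <- igraph::ecount(igraph::induced_subgraph(net, nb))
    local[i] <- 2 * e / (k * (k - 1))
  }
  mean(local)
}

#' Exact edge betweenness
#'
#' Brandes-style exact edge betweenness on the unweighted graph (similarity
#' weights gate edge existence only; shortest-path ties are split
#' fractionally, each unordered node pair counted once).
#'
#' @param net an `igraph` graph.
#' @return named numeric vector, one value per edge, names
#'   `"<v1>|<v2>"` with endpoint names in sorted order.
#' @export
edge_betweenness_exact <- function(net) {
  if (igraph::ecount(net) == 0L) return(setNames(numeric(), character()))
  eb <- igraph::edge_betweenness(net, directed = FALSE, weights = NA)
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  nm <- paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]),
              sep = "|")
  setNames(eb, nm)
}

#' Girvan-Newman division of a network
#'
#' Recursively removes the edge with the highest betweenness (recomputing
#' after every removal) until the network splits, then recurses on the
#' parts. A component is not divided further when
#'
#' * its clustering coefficient is at least `cc_stop` (the `>=` convention
#'   makes `cc_stop = 1` stop exactly on locally complete graphs), or
#' * it holds fewer than `min_size` interfaces (so nodes do not fall apart
#'   into dust; after a split, an undersized side is "no more divided").
#'
#' Betweenness ties on removal are broken deterministically by the
#' lexicographic (min endpoint, max endpoint) name order. Components of a
#' disconnected input are processed independently. When nodes are
#' supernodes, sizes count member interfaces, and the stopping coefficient
#' is evaluated on the underlying interface graph (`underlying`) when one
#' is supplied: node grouping is a run-time optimisation and must not
#' change where division stops.
#'
#' @param net an `igraph` graph (with optional `members` vertex attribute).
#' @param cc_stop clustering-coefficient stopping criterion in `[0, 1]`.
#' @param min_size minimum cluster size (interfaces), default 5.
#' @param underlying optional original (un-condensed) interface network;
#'   the clustering-coefficient stop is evaluated on the subgraph induced
#'   by a component's member interfaces instead of on the condensed
#'   component itself.
#' @return list of `igraph` subnetworks (the final communities).
#' @export
girvan_newman_divide <- function(net, cc_stop, min_size = 5,
                                 underlying = NULL) {
  comps <- decompose_named(net)
  if (length(comps) > 1L) {
    return(do.call(c, lapply(comps, girvan_newman_divide, cc_stop = cc_stop,
                             min_size = min_size, underlying = underlying)))
  }
  g <- comps[[1L]]
  if (igraph::vcount(g) < 2L || igraph::ecount(g) == 0L) return(list(g))
  if (n_member_interfaces(g) < min_size) return(list(g))
  cc <- if (is.null(underlying)) clustering_coefficient(g) else
    clustering_coefficient(igraph::induced_subgraph(
      underlying, unlist(node_members(g))))
  if (cc >= cc_stop) return(list(g))
  gg <- g
  while (igraph::count_components(gg) == 1L) {
    eb <- edge_betweenness_exact(gg)
    drop <- names(eb)[order(-eb, names(eb))][1L]
    gg <- igraph::delete_edges(gg, igraph::get_edge_ids(
      gg, strsplit(drop, "|", fixed = TRUE)[[1L]]))
  }
  do.call(c, lapply(decompose_named(gg), girvan_newman_divide,
                    cc_stop = cc_stop, min_size = min_size,
                    underlying = underlying))
}

decompose_named <- function(g) {
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) {
    igraph::induced_subgraph(g, which(comp$membership == k))
  })
}

#' Condense a network by grouping highly similar nodes
#'
#' Iteratively merges the pair of nodes joined by the currently
#' highest-weight edge while any edge weight reaches `sim_threshold`
#' (processing the most similar nodes first; weight ties broken by
#' lexicographic endpoint names). The merged supernode inherits each
#' neighbour with weight equal to the maximum (`merge_mode = "max"`) or
#' minimum (`"min"`) of the merged nodes' existing edges to that
#' neighbour; member lists are concatenated so the condensation conserves
#' interface membership exactly.
#'
#' @param net an `igraph` graph with `weight` edge attribute.
#' @param sim_threshold grouping threshold (edges with weight `>=` it are
#'   collapsed).
#' @param merge_mode `"max"` (default; performs best downstream) or
#'   `"min"`.
#' @return the condensed `igraph` graph; supernodes are named after their
#'   lexicographically first member and carry the merged `members` list.
#' @export
group_nodes <- function(net, sim_threshold, merge_mode = c("max", "min")) {
  merge_mode <- match.arg(merge_mode)
  comb <- if (merge_mode == "max") max else min
  g <- net
  if (is.null(igraph::vertex_attr(g, "members"))) {
    g <- igraph::set_vertex_attr(g, "members", value = as.list(igraph::V(g)$name))
  }
  repeat {
    if (igraph::ecount(g) == 0L) break
    w <- igraph::E(g)$weight
    if (max(w) < sim_threshold) break
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    e1 <- pmin(ends[, 1L], ends[, 2L]); e2 <- pmax(ends[, 1L], ends[, 2L])
    pick <- order(-w, e1, e2)[1L]
    u <- e1[pick]; v <- e2[pick]
    vn <- igraph::V(g)$name
    mapping <- seq_along(vn)
    mapping[match(v, vn)] <- match(u, vn)
    # relabel to consecutive ids as contract() requires
    mapping <- match(mapping, sort(unique(mapping)))
    g <- igraph::contract(g, mapping, vertex.attr.comb = list(
      name = function(x) min(x),
      members = function(m) sort(unique(unlist(m)))))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(weight = comb))
    # contract() wraps members; keep them as a plain list of character vectors
    mm <- igraph::vertex_attr(g, "members")
    g <- igraph::set_vertex_attr(g, "members", value = mm)
  }
  g
}

#' Cluster interfaces by staged node grouping + Girvan-Newman division
#'
#' The full clustering procedure: the similarity network is processed in
#' grouping stages of increasing similarity threshold (default 0.80, 0.85,
#' 0.90, 0.95, 1.00). At each stage, every current community's subnetwork
#' (original interface nodes) is condensed by [group_nodes()] at the stage
#' threshold and divided by [girvan_newman_divide()]; supernodes are
#' expanded back to interfaces between stages. After the staged cycles the
#' resulting communities are re-divided once more without any node
#' grouping, giving the final interface clusters. The output partitions
#' the input interfaces exactly and is deterministic.
#'
#' @param net an `igraph` similarity network from [build_network()] (or a
#'   `piface_simtable` / similarity matrix, converted with
#'   `edge_threshold`).
#' @param cc_stop clustering-coefficient stopping criterion (best-performing
#'   published setting: 1.0).
#' @param grouping_steps similarity thresholds of the staged grouping,
#'   processed in increasing order.
#' @param merge_mode supernode edge-weight combination, `"max"` or `"min"`.
#' @param min_size minimum cluster size (interfaces).
#' @param edge_threshold used only when `net` is not already a graph.
#' @param sim similarity source for representative selection (defaults to
#'   edge weights of `net`).
#' @return a `piface_clusterset`: list with `clusters` (list of sorted
#'   interface-id vectors, ordered by first member), `representative`
#'   (character vector, one per cluster), `params` (including the
#'   conventional tag such as `"100_5_max"`).
#' @export
cluster_interfaces <- function(net, cc_stop = 1.0,
                               grouping_steps = c(0.80, 0.85, 0.90, 0.95, 1.00),
                               merge_mode = c("max", "min"), min_size = 5,
                               edge_threshold = 0.75, sim = NULL) {
  merge_mode <- match.arg(merge_mode)
  if (!inherits(net, "igraph")) {
    if (is.null(sim)) sim <- net
    net <- build_network(net, edge_threshold)
  }
  g0 <- net
  communities <- lapply(decompose_named(g0), function(g) igraph::V(g)$name)
  for (thr in sort(grouping_steps)) {
    nxt <- list()
    for (comm in communities) {
      sub <- igraph::induced_subgraph(g0, comm)
      sub <- igraph::set_vertex_attr(sub, "members",
                                     value = as.list(igraph::V(sub)$name))
      parts <- girvan_newman_divide(group_nodes(sub, thr, merge_mode),
                                    cc_stop, min_size, underlying = g0)
      nxt <- c(nxt, lapply(parts, function(p) sort(unlist(node_members(p)))))
    }
    communities <- nxt
  }
  final <- list()
  for (comm in communities) {
    sub <- igraph::induced_subgraph(g0, comm)
    sub <- igraph::set_vertex_attr(sub, "members",
                                   value = as.list(igraph::V(sub)$name))
    parts <- girvan_newman_divide(sub, cc_stop, min_size)
    final <- c(final, lapply(parts, function(p) sort(unlist(node_members(p)))))
  }
  final <- final[order(vapply(final, `[`, character(1L), 1L))]
  simm <- similarity_for_representatives(sim, g0)
  reps <- vapply(final, select_representative, character(1L), sim = simm)
  step_pct <- if (length(grouping_steps) >= 2L) {
    round(100 * min(diff(sort(grouping_steps))))
  } else 0L
  structure(list(
    clusters = final,
    representative = reps,
    params = list(cc_stop = cc_stop, grouping_steps = sort(grouping_steps),
                  merge_mode = merge_mode, min_size = min_size,
                  tag = sprintf("%d_%d_%s", round(100 * cc_stop), step_pct,
                                merge_mode))),
    class = "piface_clusterset")
}

similarity_for_representatives <- function(sim, g0) {
  if (!is.null(sim)) return(similarity_matrix(sim))
  nms <- igraph::V(g0)$name
  m <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  diag(m) <- 1
  if (igraph::ecount(g0) > 0L) {
    ends <- igraph::ends(g0, igraph::E(g0), names = TRUE)
    m[ends] <- igraph::E(g0)$weight
    m[ends[, c(2L, 1L), drop = FALSE]] <- igraph::E(g0)$weight
  }
  m
}

#' @export
print.piface_clusterset <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("piface_clusterset [", x$params$tag, "]: ", length(sizes),
      " clusters over ", sum(sizes), " interfaces (",
      sum(sizes == 1L), " singletons)\n", sep = "")
  invisible(x)
}

#' Representative interface of a cluster
#'
#' The member with the highest mean similarity to all other members (ties
#' broken by name order); a singleton represents itself.
#'
#' @param cluster character vector of member interface ids.
#' @param sim similarity matrix (or `piface_simtable`); absent pairs count
#'   as similarity 0.
#' @return the representative's interface id.
#' @export
select_representative <- function(cluster, sim) {
  cluster <- sort(cluster)
  if (length(cluster) == 0L) stop("empty cluster")
  if (length(cluster) == 1L) return(cluster)
  m <- similarity_matrix(sim)
  missing <- setdiff(cluster, rownames(m))
  if (length(missing) > 0L) {
    ext <- matrix(0, length(missing), ncol(m),
                  dimnames = list(missing, colnames(m)))
    m <- rbind(m, ext)
    m <- cbind(m, rbind(t(ext), matrix(0, length(missing), length(missing),
                                       dimnames = list(missing, missing))))
    diag(m) <- 1
  }
  sub <- m[cluster, cluster, drop = FALSE]
  mean_sim <- (rowSums(sub) - diag(sub)) / (length(cluster) - 1L)
  cluster[order(-mean_sim, cluster)][1L]
}

#' Cluster membership as a named vector
#'
#' @param clusters a `piface_clusterset`.
#' @return named integer vector: interface id -> cluster index.
#' @export
cluster_membership <- function(clusters) {
  idx <- rep(seq_along(clusters$clusters), lengths(clusters$clusters))
  setNames(idx, unlist(clusters$clusters))
}

#' Write / read a cluster set as TSV
#'
#' Format: `cluster_id<TAB>representative<TAB>member1,member2,...`.
#'
#' @param clusters a `piface_clusterset`.
#' @param path TSV path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(cluster_id = seq_along(clusters$clusters),
                   representative = clusters$representative,
                   members = vapply(clusters$clusters, paste,
                                    character(1L), collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
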