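#' Silhouette index of an interface clustering
#'
#' Dissimilarity is `d(i, j) = 1 - similarity(i, j)`, with pairs absent
#' from the similarity data (failed the size gate or fell below the edge
#' threshold) treated as similarity 0, i.e. maximally dissimilar — the
#' conservative completion of a sparse similarity table. For each
#' interface, `a(i)` is the mean dissimilarity to its own cluster's other
#' members, `b(i)` the minimum over other clusters of the mean
#' dissimilarity to that cluster, and
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Members of singleton clusters
#' score `s(i) = 0` (Rousseeuw's convention). The overall index is the
#' mean of `s(i)` over all interfaces.
#'
#' @param clusters a `piface_clusterset`, or a list of character vectors.
#' @param sim similarity matrix or `piface_simtable` covering the
#'   clustered interfaces.
#' @return `piface_silhouette`: list with `per_interface_s`, `a_values`,
#'   `b_values` (named vectors) and `overall`.
#' @export
silhouette_index <- function(clusters, sim) {
  cl <- if (inherits(clusters, "piface_clusterset")) clusters$clusters else clusters
  if (length(cl) < 2L) stop("silhouette needs at least 2 clusters (b is undefined)")
  all_ids <- unlist(cl)
  if (anyDuplicated(all_ids)) stop("clusters overlap: not a partition")
  m <- similarity_matrix(sim)
  missing <- setdiff(all_ids, rownames(m))
  if (length(missing) > 0L) {
    full <- matrix(0, length(all_ids), length(all_ids),
                   dimnames = list(all_ids, all_ids))
    common <- intersect(all_ids, rownames(m))
    full[common, common] <- m[common, common]
    diag(full) <- 1
    m <- full
  }
  d <- 1 - m
  a <- b <- s <- setNames(rep(NA_real_, length(all_ids)), all_ids)
  for (ci in seq_along(cl)) {
    own <- cl[[ci]]
    others <- cl[-ci]
    for (id in own) {
      if (length(own) == 1L) { a[id] <- 0; b[id] <- 0; s[id] <- 0; next }
      a[id] <- mean(d[id, setdiff(own, id)])
      b[id] <- min(vapply(others, function(o) mean(d[id, o, drop = FALSE]),
                          numeric(1L)))
      denom <- max(a[id], b[id])
      s[id] <- if (denom > 0) (b[id] - a[id]) / denom else 0
    }
  }
  structure(list(per_interface_s = s, a_values = a, b_values = b,
                 overall = mean(s)),
            class = "piface_silhouette")
}

#' @export
print.piface_silhouette <- function(x, ...) {
  cat("piface_silhouette: overall ", formatC(x$overall, digits = 3, format = "f"),
      " over ", length(x$per_interface_s), " interfaces\n", sep = "")
  invisible(x)
}

#' Evaluate a grid of clustering parameters by silhouette
#'
#' Runs [cluster_interfaces()] for every grid cell and ranks the cells by
#' overall silhouette (ties broken by cell tag, so the ranking is stable).
#' Cells producing a single cluster, for which the silhouette is
#' undefined, score `NA` and rank last.
#'
#' @param sim similarity source (`piface_simtable` or matrix).
#' @param cc_stop_values clustering-coefficient stopping criteria to try.
#' @param step_values grouping-step increments in percent (5 means
#'   thresholds 0.80, 0.85, ..., 1.00).
#' @param merge_modes `"max"`, `"min"` or both.
#' @param edge_threshold,min_size passed to [cluster_interfaces()].
#' @return data frame `tag`, `cc_stop`, `step`, `merge_mode`,
#'   `n_clusters`, `n_singletons`, `silhouette`, ranked best-first.
#' @export
parameter_grid_eval <- function(sim, cc_stop_values = c(1.0, 0.9, 0.8),
                                step_values = 5, merge_modes = c("max", "min"),
                                edge_threshold = 0.75, min_size = 5) {
  net <- build_network(sim, edge_threshold)
  grid <- expand.grid(cc_stop = cc_stop_values, step = step_values,
                      merge_mode = merge_modes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    steps <- seq(0.80, 1.00, by = grid$step[r] / 100)
    cs <- cluster_interfaces(net, cc_stop = grid$cc_stop[r],
                             grouping_steps = steps,
                             merge_mode = grid$merge_mode[r],
                             min_size = min_size, sim = sim)
    sil <- if (length(cs$clusters) >= 2L) silhouette_index(cs, sim)$overall
    else NA_real_
    data.frame(tag = cs$params$tag, cc_stop = grid$cc_stop[r],
               step = grid$step[r], merge_mode = grid$merge_mode[r],
               n_clusters = length(cs$clusters),
               n_singletons = sum(lengths(cs$clusters) == 1L),
               silhouette = sil, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$silhouette), -Inf, out$silhouette), out$tag), ,
      drop = FALSE]
}

#' Cluster size distribution
#'
#' @param clusters a `piface_clusterset` or list of member vectors.
#' @return named integer vector: size -> number of clusters of that size;
#'   `sum(size * count)` equals the number of clustered interfaces.
#' @export
cluster_size_distribution <- function(clusters) {
  cl <- if (inherits(clusters, "piface_clusterset")) clusters$clusters else clusters
  tab <- table(lengths(cl))
  setNames(as.integer(tab), names(tab))
}
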