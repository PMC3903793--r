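test_that("build_network applies the edge threshold and keeps isolated nodes", {
  nodes <- sprintf("I%d", 1:5)
  tab <- data.frame(iface1 = c("I1", "I2"), iface2 = c("I2", "I3"),
                    similarity = c(0.80, 0.70))
  g <- build_network(tab, edge_threshold = 0.75, nodes = nodes)
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.80)
  empty <- build_network(tab[0, ], edge_threshold = 0.75, nodes = nodes)
  expect_equal(igraph::ecount(empty), 0L)
  expect_equal(igraph::vcount(empty), 5L)
})

test_that("a planted 2-block matrix yields 2 connected components", {
  pg <- planted_partition_graph(c(5, 5), 1, 0, seed = 2)
  expect_equal(igraph::count_components(pg$network), 2L)
})

test_that("clustering coefficient: clique 1, path 0, hand case by triples", {
  tri <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  expect_equal(clustering_coefficient(tri), 1)
  path3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(clustering_coefficient(path3), 0)
  # 4 nodes, edges AB BC CD AC: oracle by triple enumeration
  adj <- matrix(0L, 4, 4)
  adj[cbind(c(1, 2, 3, 1), c(2, 3, 4, 3))] <- 1L
  adj <- adj + t(adj)
  expect_equal(clustering_coefficient(graph_from_adj(adj)),
               oracle_clustering_coefficient(adj))
})

test_that("clustering coefficient equals the triple-enumeration oracle on random graphs", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.9))
    expect_equal(clustering_coefficient(graph_from_adj(adj)),
                 oracle_clustering_coefficient(adj))
  }
})

test_that("a bridge between cliques dominates betweenness; clique edges tie", {
  adj <- matrix(0L, 10, 10)
  adj[1:5, 1:5] <- 1L; adj[6:10, 6:10] <- 1L; diag(adj) <- 0L
  adj[5, 6] <- adj[6, 5] <- 1L
  eb <- edge_betweenness_exact(graph_from_adj(adj))
  bridge <- eb[["n05|n06"]]
  expect_true(all(bridge > eb[names(eb) != "n05|n06"]))
  clique <- graph_from_adj(matrix(1L, 5, 5) - diag(5L))
  ebc <- edge_betweenness_exact(clique)
  expect_true(all(abs(ebc - ebc[1]) < 1e-9))
})

test_that("edge betweenness equals brute-force path enumeration on 12-node graphs", {
  set.seed(17)
  for (rep in 1:3) {
    adj <- random_adj(12, 0.3)
    eb <- edge_betweenness_exact(graph_from_adj(adj))
    oracle <- oracle_edge_betweenness(adj)
    nm <- sub("n0?(\\d+)\\|n0?(\\d+)", "\\1|\\2", names(eb))
    expect_equal(unname(eb), unname(oracle[nm]), tolerance = 1e-9)
  }
})

test_that("Girvan-Newman splits two 6-cliques joined by a bridge exactly", {
  adj <- matrix(0L, 12, 12)
  adj[1:6, 1:6] <- 1L; adj[7:12, 7:12] <- 1L; diag(adj) <- 0L
  adj[6, 7] <- adj[7, 6] <- 1L
  g <- graph_from_adj(adj)
  parts <- girvan_newman_divide(g, cc_stop = 1.0)
  sets <- lapply(parts, function(p) sort(igraph::V(p)$name))
  expect_length(sets, 2L)
  expect_setequal(sets, list(sprintf("n%02d", 1:6), sprintf("n%02d", 7:12)))
})

test_that("a 5-clique is returned whole at cc_stop = 1 (>= convention)", {
  clique <- graph_from_adj(matrix(1L, 5, 5) - diag(5L))
  parts <- girvan_newman_divide(clique, cc_stop = 1.0)
  expect_length(parts, 1L)
  expect_equal(igraph::vcount(parts[[1]]), 5L)
})

test_that("after a 4-vs-6 split only the 6-node side divides further", {
  # 4-path -- bridge -- {two triangles joined by an edge}
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4),            # path a1..a4 (cc 0)
                 c(4, 5),                              # bridge
                 c(5, 6), c(6, 7), c(5, 7),            # triangle x
                 c(7, 8),                              # intra-6 link
                 c(8, 9), c(9, 10), c(8, 10))          # triangle y
  adj <- matrix(0L, 10, 10)
  adj[edges] <- 1L; adj <- adj + t(adj)
  parts <- girvan_newman_divide(graph_from_adj(adj), cc_stop = 1.0,
                                min_size = 5)
  sets <- lapply(parts, function(p) sort(igraph::V(p)$name))
  # the 4-node side survives intact even though its coefficient is 0
  expect_true(any(vapply(sets, identical, logical(1), sprintf("n%02d", 1:4))))
  expect_true(all(lengths(sets) %in% c(3, 4)))
})

test_that("cc_stop = 0 returns every connected component undivided", {
  set.seed(23)
  adj <- random_adj(10, 0.25)
  g <- graph_from_adj(adj)
  parts <- girvan_newman_divide(g, cc_stop = 0)
  expect_equal(length(parts), igraph::count_components(g))
})

test_that("group_nodes merges per the Fig-1c max rule and conserves members", {
  tab <- data.frame(iface1 = c("G", "G", "H"), iface2 = c("H", "X", "X"),
                    similarity = c(0.9, 0.5, 0.7))
  g <- build_network(tab, 0)
  gg <- group_nodes(g, 0.8, "max")
  expect_equal(igraph::vcount(gg), 2L)
  mem <- piface:::node_members(gg)
  expect_setequal(unlist(mem), c("G", "H", "X"))
  expect_equal(igraph::E(gg)$weight, 0.7)  # max of 0.5 and 0.7
  gmin <- group_nodes(g, 0.8, "min")
  expect_equal(igraph::E(gmin)$weight, 0.5)
  # no edge above threshold -> unchanged
  same <- group_nodes(g, 0.95, "max")
  expect_equal(igraph::vcount(same), 3L)
  # chain a-b-c with 0.95, 0.85 collapses fully at threshold 0.8
  chain <- build_network(data.frame(iface1 = c("a", "b"), iface2 = c("b", "c"),
                                    similarity = c(0.95, 0.85)), 0)
  one <- group_nodes(chain, 0.8, "max")
  expect_equal(igraph::vcount(one), 1L)
  expect_setequal(unlist(piface:::node_members(one)), c("a", "b", "c"))
})

test_that("cluster_interfaces recovers planted communities and partitions inputs", {
  pg <- planted_partition_graph(c(6, 7, 6, 8), p_in = 1, p_out = 0.05,
                                seed = 11)
  cs <- cluster_interfaces(pg$network, cc_stop = 1.0)
  expect_s3_class(cs, "piface_clusterset")
  # exact recovery of the 4 planted blocks
  expect_length(cs$clusters, 4L)
  for (cl in cs$clusters) {
    expect_length(unique(pg$membership[cl]), 1L)
  }
  # partition invariant
  expect_setequal(unlist(cs$clusters), names(pg$membership))
  expect_false(anyDuplicated(unlist(cs$clusters)) > 0)
  expect_identical(cs$params$tag, "100_5_max")
})

test_that("three mutually similar interfaces form one cluster", {
  tab <- data.frame(iface1 = c("i1", "i1", "i2"), iface2 = c("i2", "i3", "i3"),
                    similarity = 0.9)
  cs <- cluster_interfaces(tab, cc_stop = 1.0)
  expect_length(cs$clusters, 1L)
  expect_setequal(cs$clusters[[1]], c("i1", "i2", "i3"))
})

test_that("grouping conserves total interface membership at every threshold", {
  pg <- planted_partition_graph(c(5, 5, 5), 0.8, 0.2, seed = 9)
  for (thr in c(0.8, 0.9, 0.99)) {
    gg <- group_nodes(pg$network, thr, "max")
    expect_setequal(unlist(piface:::node_members(gg)), names(pg$membership))
  }
})

test_that("representatives maximise mean similarity with name tie-breaks", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(m) <- 1
  m["a", "b"] <- m["b", "a"] <- 0.9
  m["b", "c"] <- m["c", "b"] <- 0.9
  m["a", "c"] <- m["c", "a"] <- 0.1
  expect_identical(select_representative(c("a", "b", "c"), m), "b")
  expect_identical(select_representative("z", m), "z")
  clique <- matrix(0.8, 3, 3, dimnames = list(c("x", "y", "w"), c("x", "y", "w")))
  diag(clique) <- 1
  expect_identical(select_representative(c("y", "x", "w"), clique), "w")
})

test_that("cluster TSV round trip preserves the partition", {
  pg <- planted_partition_graph(c(6, 6), 1, 0, seed = 3)
  cs <- cluster_interfaces(pg$network, cc_stop = 1.0)
  p <- tempfile(fileext = ".tsv")
  write_clusters_tsv(cs, p)
  back <- read_clusters_tsv(p)
  expect_identical(nrow(back), length(cs$clusters))
  expect_setequal(unlist(strsplit(back$members, ",")), unlist(cs$clusters))
  expect_identical(back$representative, unname(cs$representative))
})
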