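test_that("edge thresholding keeps weights >= the cut and sidelines stranded nodes", {
  edges <- data.frame(mirna_a = c("a", "b", "c"), mirna_b = c("b", "c", "d"),
                      weight = c(2L, 3L, 5L), stringsAsFactors = FALSE)
  net <- toy_network(edges)
  thr <- threshold_edges(net, 2.9)
  expect_equal(sort(thr$edges$weight), c(3, 5))
  expect_true("a" %in% thr$isolated)
  expect_false("a" %in% thr$nodes$mirna_id)

  all1 <- toy_network(data.frame(mirna_a = "a", mirna_b = "b", weight = 1L))
  expect_equal(nrow(threshold_edges(all1, 2.9)$edges), 0)
  expect_equal(threshold_edges(net, 0)$edges, net$edges)
})

test_that("MCL separates disconnected components and clusters trivial graphs", {
  tri2 <- toy_network(data.frame(
    mirna_a = c("a", "a", "b", "x", "x", "y"),
    mirna_b = c("b", "c", "c", "y", "z", "z"),
    weight = 1L, stringsAsFactors = FALSE))
  cl <- mcl_cluster(tri2)
  expect_length(cl$clusters, 2)
  expect_setequal(lengths(cl$clusters), c(3, 3))
  expect_true(setequal(cl$clusters[[1]], c("a", "b", "c")) ||
              setequal(cl$clusters[[1]], c("x", "y", "z")))

  single <- toy_network(data.frame(mirna_a = "a", mirna_b = "b", weight = 1L))
  cl1 <- mcl_cluster(single)
  expect_length(cl1$clusters, 1)
  expect_setequal(cl1$clusters[[1]], c("a", "b"))

  empty <- threshold_edges(single, 10)
  expect_length(mcl_cluster(empty)$clusters, 0)
})

test_that("MCL recovers the two cliques of a barbell and agrees with the reference", {
  cliq <- function(ids, w = 3L) {
    cmb <- t(combn(ids, 2))
    data.frame(mirna_a = cmb[, 1], mirna_b = cmb[, 2], weight = w,
               stringsAsFactors = FALSE)
  }
  left <- sprintf("L%02d", 1:10); right <- sprintf("R%02d", 1:10)
  edges <- rbind(cliq(left), cliq(right),
                 data.frame(mirna_a = "L01", mirna_b = "R01", weight = 1L))
  net <- toy_network(edges)
  cl <- mcl_cluster(net)
  expect_length(cl$clusters, 2)
  expect_setequal(cl$clusters[[1]], if ("L01" %in% cl$clusters[[1]]) left else right)

  A <- adjacency_from_edges(edges)
  ref <- ref_mcl(A)
  memb <- cl$membership[rownames(A)]
  # identical partitions up to label permutation
  expect_equal(length(unique(ref)), length(unique(memb)))
  tab <- table(memb, ref)
  expect_equal(sum(apply(tab, 1, max)), length(memb))
})

test_that("MCL output is a partition, respects components, and survives relabelling", {
  set.seed(55)
  for (rep in 1:5) {
    edges <- random_edges(20, p = 0.2)
    if (nrow(edges) == 0) next
    net <- toy_network(edges)
    cl <- mcl_cluster(net)
    # partition: disjoint and covering
    members <- unlist(cl$clusters)
    expect_equal(sort(members), sort(net$nodes$mirna_id))
    expect_equal(anyDuplicated(members), 0)
    # nodes in different components never share a cluster
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
    comp <- igraph::components(g)$membership
    for (clust in cl$clusters) {
      expect_equal(length(unique(comp[clust])), 1)
    }
    # node relabelling leaves the partition intact
    ids <- sort(unique(c(edges$mirna_a, edges$mirna_b)))
    relab <- setNames(sprintf("z%02d", rev(seq_along(ids))), ids)
    edges2 <- transform(edges, mirna_a = relab[mirna_a], mirna_b = relab[mirna_b])
    cl2 <- mcl_cluster(toy_network(edges2))
    part1 <- lapply(cl$clusters, function(x) sort(unname(relab[x])))
    part2 <- lapply(cl2$clusters, sort)
    expect_setequal(vapply(part1, paste, character(1), collapse = ","),
                    vapply(part2, paste, character(1), collapse = ","))
  }
})

test_that("cluster reports rank dominant features by intra-edge support and flag thick edges", {
  edges <- data.frame(
    mirna_a = c("a", "a", "b"), mirna_b = c("b", "c", "c"),
    weight = c(3L, 3L, 5L), p_value = 0.001,
    shared_features = c("P1;P2;P3", "P1;P4;P5", "P1;P2;P4;P5;P6"),
    stringsAsFactors = FALSE)
  net <- network_from_edges(edges)
  cl <- mcl_cluster(net)
  s <- cluster_summary(cl, 1)
  expect_equal(s$dominant_features$feature_id[1], "P1")
  expect_equal(s$dominant_features$n_edges[1], 3)
  expect_equal(nrow(s$max_weight_edges), 1)
  expect_equal(s$max_weight_edges$weight, 5)
  # a cluster whose every edge shares pathway P ranks P first with count |E|
  expect_equal(s$dominant_features$n_edges[s$dominant_features$feature_id == "P1"],
               nrow(s$intra_edges))
})
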