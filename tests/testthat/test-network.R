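test_that("pair-overlap p-value is exact, symmetric, and monotone in the overlap", {
  expect_equal(pair_overlap_p(400, 2, 3, 0), 1)
  # two pathway sets of 2 and 3 sharing one pathway among 400
  expect_equal(pair_overlap_p(400, 2, 3, 1), 1194 / 79800, tolerance = 1e-14)
  expect_equal(pair_overlap_p(400, 2, 3, 1), ref_pair_p(400, 2, 3, 1),
               tolerance = 1e-13)
  set.seed(29)
  for (rep in 1:20) {
    N <- sample(5:25, 1)  # the combinatorial oracle is exact in this range
    n <- sample.int(N, 1); m <- sample.int(N, 1)
    x <- sample.int(min(n, m), 1)
    expect_equal(pair_overlap_p(N, n, m, x), pair_overlap_p(N, m, n, x),
                 tolerance = 1e-14)
    expect_equal(pair_overlap_p(N, n, m, x), ref_pair_p(N, n, m, x),
                 tolerance = 1e-12)
  }
  p_seq <- vapply(0:3, function(x) pair_overlap_p(50, 5, 8, x), numeric(1))
  expect_true(all(diff(p_seq) <= 0))
  expect_error(pair_overlap_p(10, 4, 3, 4), "min")
  expect_error(pair_overlap_p(10, 12, 3, 1), "universe")
})

test_that("the two-miRNA worked example gives one weight-1 edge through the shared pathway", {
  ann <- list(X = c("P1", "P2"), Y = c("P2", "P5", "P8"))
  net <- build_network(ann, N = 400)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$mirna_a, net$edges$mirna_b), c("X", "Y"))
  expect_equal(net$edges$weight, 1)
  expect_equal(net$edges$shared_features, "P2")
  expect_equal(net$edges$p_value, 1194 / 79800, tolerance = 1e-12)
  # disjoint feature sets produce no edge
  net2 <- build_network(list(A = "P1", B = "P2"), N = 400)
  expect_equal(nrow(net2$edges), 0)
  expect_setequal(net2$isolated, c("A", "B"))
})

test_that("network construction is input-order invariant and weights recompute from annotations", {
  set.seed(33)
  ann <- lapply(setNames(1:12, sprintf("m%02d", 1:12)), function(i) {
    sample(sprintf("P%02d", 1:30), sample(3:8, 1))
  })
  net1 <- build_network(ann, N = 400)
  net2 <- build_network(ann[sample(length(ann))], N = 400)
  expect_equal(net1$edges, net2$edges)
  for (i in seq_len(nrow(net1$edges))) {
    a <- net1$edges$mirna_a[i]; b <- net1$edges$mirna_b[i]
    expect_equal(net1$edges$weight[i],
                 length(intersect(ann[[a]], ann[[b]])))
    expect_lt(net1$edges$p_value[i], net1$alpha)
  }
  expect_error(build_network(ann, N = 5), "universe")
  expect_error(build_network(list(a = character(0)), N = 10), "empty")
})

test_that("most-targeted-gene tally counts distinct miRNAs with the min-support rule", {
  sets <- list(m1 = c("g1", "g2"), m2 = "g1", m3 = "g1")
  out <- most_targeted_genes(sets)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$frequency, 3)
  expect_equal(nrow(most_targeted_genes(list(m1 = "a", m2 = "b"))), 0)
  # ranking: count desc, gene id asc within ties; top cut respected
  sets2 <- list(m1 = c("gB", "gA"), m2 = c("gB", "gA"), m3 = "gC", m4 = "gC")
  out2 <- most_targeted_genes(sets2, top = 2)
  expect_equal(out2$gene_id, c("gA", "gB"))
})

test_that("a planted hub gene tops the tally at its planted frequency", {
  cfg <- sim_config(n_mirnas = 200, n_responsive = 25, n_blocks = 1,
                    block_size = 5, source_agreement = 1,
                    hub_gene_mirnas = 19, seed = 77)
  st <- simulate_study(cfg)
  cons <- consensus_targets(st$pred_a, st$pred_b,
                            mirna_ids = names(st$truth_targets))
  out <- most_targeted_genes(cons)
  expect_equal(out$gene_id[1], "GHUB")
  # brute-force scan over the raw sets
  expect_equal(out$frequency[1],
               sum(vapply(cons, function(s) "GHUB" %in% s, logical(1))))
  expect_equal(out$frequency[1], 19)
})
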