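test_that("configuration validation names the offending field", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_mirnas = 0), "n_mirnas")
  expect_error(sim_config(n_responsive = 50, n_mirnas = 10), "n_responsive")
  expect_error(sim_config(source_agreement = 1.2), "source_agreement")
  expect_error(sim_config(planted_log2fc = 0.5), "planted_log2fc")
  expect_error(sim_config(pathway_size_range = c(10, 50000)), "pathway_size_range")
  expect_error(sim_config(n_responsive = 10, n_blocks = 3, block_size = 5),
               "block_size")
})

test_that("expression simulation has the configured shape, positivity, and planted truth", {
  cfg <- sim_config(n_mirnas = 2006, n_replicates_per_group = 2,
                    n_responsive = 100, seed = 7)
  sim <- simulate_expression(cfg)
  expect_equal(dim(sim$matrix), c(2006, 4))
  expect_true(all(sim$matrix > 0))
  expect_equal(nrow(sim$truth), 100)
  expect_setequal(unique(sim$design$group), c("treated", "control"))

  none <- simulate_expression(sim_config(n_mirnas = 100, n_responsive = 0, seed = 1))
  expect_equal(nrow(none$truth), 0)

  # planted log2 ratios centred on the planted effect, null miRNAs on zero
  cfg2 <- sim_config(n_mirnas = 3000, n_responsive = 300, planted_log2fc = 2,
                     noise_sd = 0.25, seed = 19)
  s2 <- simulate_expression(cfg2)
  lr <- log2(apply(s2$matrix[, 1:2], 1, mirnet::geometric_mean) /
             apply(s2$matrix[, 3:4], 1, mirnet::geometric_mean))
  planted <- rownames(s2$matrix) %in% s2$truth$mirna_id
  expect_equal(mean(abs(lr[planted])), 2, tolerance = 0.05)
  expect_equal(mean(lr[!planted]), 0, tolerance = 0.05)
  expect_equal(sign(lr[planted][match(s2$truth$mirna_id,
                                      rownames(s2$matrix)[planted])]),
               sign(s2$truth$true_log2fc), ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical files; different seeds differ", {
  cfg <- sim_config(n_mirnas = 60, n_responsive = 8, n_blocks = 1,
                    block_size = 4, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_study(cfg), d1)
  p2 <- write_simulation(simulate_study(cfg), d2)
  p3 <- write_simulation(simulate_study(sim_config(n_mirnas = 60, n_responsive = 8,
                                                   n_blocks = 1, block_size = 4,
                                                   seed = 100)), d3)
  for (nm in names(p1)) {
    expect_equal(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])))
  }
  expect_false(identical(unname(tools::md5sum(p1[["matrix"]])),
                         unname(tools::md5sum(p3[["matrix"]]))))
})

test_that("pathway collection honours its config and blocks get disjoint pathways", {
  cfg <- sim_config(n_mirnas = 100, n_responsive = 20, n_pathways = 400,
                    n_blocks = 2, block_size = 6, seed = 3)
  pw <- simulate_pathways(cfg)
  expect_length(pw$db, 400)
  expect_true(all(lengths(pw$db) >= 20 & lengths(pw$db) <= 200))
  expect_length(intersect(pw$block_pathways[[1]], pw$block_pathways[[2]]), 0)
  # a single-miRNA block cannot form a within-block pair
  cfg1 <- sim_config(n_mirnas = 50, n_responsive = 4, n_blocks = 1,
                     block_size = 1, seed = 3)
  st1 <- simulate_study(cfg1)
  expect_equal(sum(st1$blocks$block == 1, na.rm = TRUE), 1)
})

test_that("consensus thinning follows the binomial expectation of source agreement", {
  # agreement 1 and 0 bracket the behaviour deterministically
  cfg1 <- sim_config(n_mirnas = 50, n_responsive = 4, n_blocks = 1,
                     block_size = 2, source_agreement = 0, seed = 5)
  st0 <- simulate_study(cfg1)
  cons0 <- consensus_targets(st0$pred_a, st0$pred_b,
                             mirna_ids = names(st0$truth_targets))
  expect_true(all(lengths(cons0) == 0))

  # agreement 0.5: mean consensus fraction over seeds within binomial error
  fracs <- c()
  for (seed in 1:20) {
    cfg <- sim_config(n_mirnas = 30, n_responsive = 2, n_blocks = 0,
                      block_size = 0, n_background_targets = 40,
                      source_agreement = 0.5, seed = seed)
    st <- simulate_study(cfg)
    cons <- consensus_targets(st$pred_a, st$pred_b,
                              mirna_ids = names(st$truth_targets))
    fracs <- c(fracs, lengths(cons) / lengths(st$truth_targets))
  }
  # 40 binomial(40, 0.5) draws: se of the mean ~ 0.0125
  expect_equal(mean(fracs), 0.5, tolerance = 0.05)
})
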