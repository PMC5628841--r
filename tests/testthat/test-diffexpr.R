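test_that("quantile normalization matches the hand-computed 2x2 case and is idempotent", {
  m <- cbind(s1 = c(2, 6), s2 = c(4, 8))
  rownames(m) <- c("a", "b")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(3, 7), c(3, 7)))
  expect_equal(dimnames(qn), dimnames(m))

  # already-identical columns are a fixed point
  m2 <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9))
  rownames(m2) <- letters[1:3]
  expect_equal(quantile_normalize(m2), m2)

  # column means equalized, idempotent, on random positive matrices
  set.seed(101)
  for (rep in 1:5) {
    m3 <- matrix(2^rnorm(60, 7, 2), 15, 4,
                 dimnames = list(sprintf("m%02d", 1:15), sprintf("s%d", 1:4)))
    qn3 <- quantile_normalize(m3)
    expect_equal(diff(range(colMeans(qn3))), 0, tolerance = 1e-10)
    expect_equal(quantile_normalize(qn3), qn3, tolerance = 1e-12)
    # every column carries the same sorted value multiset (no ties here)
    sorted <- apply(qn3, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
  expect_error(quantile_normalize(cbind(c(-1, 2), c(3, 4))), "positive")
})

test_that("geometric mean follows exp(mean(log(x))) and rejects bad input", {
  expect_equal(geometric_mean(c(4, 9)), 6)
  expect_equal(geometric_mean(5), 5)
  expect_equal(geometric_mean(c(2, 8, 32)), 8)
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(1, 0)), "positive")
})

test_that("signed fold change reproduces published geometric-mean ratios and is antisymmetric", {
  expect_equal(signed_fold_change(76.9, 10), 7.69)
  expect_equal(signed_fold_change(33.72, 299.95), -8.90, tolerance = 0.01)
  expect_equal(signed_fold_change(5, 5), 1)
  set.seed(7)
  a <- 2^runif(50, 0, 10); b <- 2^runif(50, 0, 10)
  expect_equal(signed_fold_change(a, b),
               ifelse(a == b, 1, -signed_fold_change(b, a)))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
  expect_error(signed_fold_change(0, 1), "positive")
})

test_that("two-sample test agrees with an independent t computation and handles degeneracy", {
  # oracle: stats::t.test on log2 data (independent of the package arithmetic)
  set.seed(11)
  for (rep in 1:10) {
    a <- 2^rnorm(4, 8, 1); b <- 2^rnorm(3, 7, 1)
    expect_equal(two_sample_test(a, b, test = "student"),
                 t.test(log2(a), log2(b), var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(two_sample_test(a, b, test = "welch"),
                 t.test(log2(a), log2(b))$p.value, tolerance = 1e-12)
  }
  expect_equal(two_sample_test(c(4, 8), c(4, 8)), 1)      # identical groups
  expect_equal(two_sample_test(c(2, 2), c(2, 2)), 1)      # zero var, zero diff
  expect_warning(p0 <- two_sample_test(c(1, 1), c(16, 16)), "zero variance")
  expect_equal(p0, 0)                                     # zero var, big diff
  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
})

test_that("responsive calling applies both cut-offs strictly", {
  rec <- data.frame(
    mirna_id = c("up_hit", "fc_fail", "p_fail", "down_hit"),
    fold_change = c(7.69, 1.5, 10, -8.9),
    p_value = c(0.000495, 0.0001, 0.2, 0.001),
    direction = c("up", "up", "up", "down"))
  out <- call_responsive(rec)
  expect_setequal(out$mirna_id, c("up_hit", "down_hit"))
  expect_equal(out$direction[out$mirna_id == "up_hit"], "up")
  expect_equal(out$direction[out$mirna_id == "down_hit"], "down")
  # boundary: p exactly at the cut and |FC| exactly at the cut are excluded
  b <- data.frame(mirna_id = c("p_edge", "fc_edge"),
                  fold_change = c(3, 2), p_value = c(0.05, 0.01),
                  direction = c("up", "up"))
  expect_equal(nrow(call_responsive(b)), 0)
})

test_that("differential table carries geometric means, signed FC and direction coherently", {
  set.seed(5)
  cfg <- sim_config(n_mirnas = 80, n_responsive = 10, seed = 5)
  sim <- simulate_expression(cfg)
  de <- differential_expression(sim$matrix, sim$design, normalize = FALSE)
  expect_equal(nrow(de), 80)
  i <- 7
  expect_equal(de$gmean_treated[i],
               geometric_mean(sim$matrix[i, sim$design$sample_id[sim$design$group == "treated"]]))
  expect_equal(de$fold_change, signed_fold_change(de$gmean_treated, de$gmean_control))
  expect_equal(de$direction, ifelse(de$fold_change > 0, "up", "down"))
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
})

test_that("null simulations give a calibrated t-test false-positive rate", {
  cfg <- sim_config(n_mirnas = 2000, n_responsive = 0, seed = 314)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$truth), 0)
  de <- differential_expression(sim$matrix, sim$design)
  frac <- mean(de$p_value < 0.05)
  # binomial sd at n = 2000 is ~0.005; allow ~4 sd
  expect_lt(abs(frac - 0.05), 0.02)
})
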