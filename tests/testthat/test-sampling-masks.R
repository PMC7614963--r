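test_that("column density hits the target acceleration with a fully sampled center", {
  center <- 29:38  # central 10 of 64 columns under the k-space centering
  for (accel in c(2, 4)) {
    d <- build_column_density(64, accel = accel)
    expect_equal(64 / sum(d$prob[1, ]), accel, tolerance = 0.005)
    # central 10 columns fully sampled (more may saturate at low R),
    # constant along rows
    expect_true(all(d$prob[1, center] == 1))
    expect_true(all(apply(d$prob, 2, function(cc) all(cc == cc[1]))))
    expect_true(all(d$prob >= 0 & d$prob <= 1))
  }
  # exactly the center saturates at R = 4
  expect_equal(sum(build_column_density(64, accel = 4)$prob[1, ] == 1), 10)
  # higher acceleration needs a wider grid than the fully sampled center
  d8 <- build_column_density(128, accel = 8)
  expect_equal(128 / sum(d8$prob[1, ]), 8, tolerance = 0.005)
  expect_true(all(d8$prob[1, 61:70] == 1))
  # R = 1 forces full sampling exactly
  expect_true(all(build_column_density(64, accel = 1)$prob == 1))
})

test_that("the cap keeps the partitioning density strictly below one", {
  d <- build_column_density(64, accel = 4, cap_epsilon = 1e-3)
  expect_equal(max(d$prob), 1 - 1e-3)
  expect_true(all(d$prob < 1))
  expect_equal(64 / sum(d$prob[1, ]), 4, tolerance = 0.005)
})

test_that("infeasible or out-of-bounds density requests error", {
  # sample budget below the fully sampled center alone
  expect_error(build_column_density(64, accel = 20, center_cols = 10),
               "center")
  expect_error(build_column_density(32, accel = 2, center_cols = 40),
               "exceeds")
  expect_error(build_bernoulli_density(16, 16, accel = 2, center_size = 20),
               "exceeds")
})

test_that("bernoulli density scales to target and respects the radial profile flag", {
  d <- build_bernoulli_density(64, 64, accel = 8)
  expect_equal(sum(d$prob), 512, tolerance = 512 * 0.005)
  # decaying profile: along the center row, probability is non-increasing
  # with column distance outside the center block
  row <- d$prob[33, ]
  right <- row[39:64]
  expect_true(all(diff(right) <= 1e-12))

  dg <- build_bernoulli_density(64, 64, accel = 1.2, low_freq_high_prob = FALSE)
  rowg <- dg$prob[33, 39:64]
  expect_true(all(diff(rowg) >= -1e-12))

  # uniform limit: no center, order 0, R = 2 gives p = 1/2 everywhere
  du <- build_bernoulli_density(64, 64, accel = 2, order = 0, center_size = 0)
  expect_true(all(abs(du$prob - 0.5) < 1e-12))
})

test_that("mask draws respect the distribution structure and are reproducible", {
  expect_true(all(sample_mask(build_column_density(16, accel = 1))$mask == 1))
  expect_true(all(sample_mask(uniform_dist(8, 8, 0))$mask == 0))

  d <- build_column_density(32, accel = 3, center_cols = 6)
  m1 <- sample_mask(d, rng_seed = 11)
  m2 <- sample_mask(d, rng_seed = 11)
  expect_identical(m1$mask, m2$mask)
  expect_true(all(m1$mask %in% c(0, 1)))
  expect_true(all(apply(m1$mask, 2, function(cc) all(cc == cc[1]))))
})

test_that("empirical column frequencies match the density (Monte Carlo)", {
  d <- build_column_density(48, accel = 4, height = 4)
  n <- 2000
  counts <- withr::with_seed(5, {
    acc <- numeric(48)
    for (i in seq_len(n)) acc <- acc + sample_mask(d)$mask[1, ]
    acc
  })
  p <- d$prob[1, ]
  se <- sqrt(p * (1 - p) / n)
  outliers <- sum(abs(counts / n - p) > 3 * se + 1e-12)
  # 3-sigma exceedances are ~0.3% likely per free column; with 38 free
  # columns more than two would indicate a miscalibrated sampler
  expect_lte(outliers, 2)
})

test_that("partitioning is exact set algebra with the documented invariants", {
  om <- matrix(c(1, 1, 1, 0), 2, 2)  # Omega = {1,2,3}
  la <- matrix(c(0, 1, 0, 1), 2, 2)  # Lambda = {2,4}
  p <- partition_sets(om, la)
  expect_equal(which(p$A), c(1L, 3L))
  expect_equal(which(p$B), 2L)
  expect_equal(partition_ratio(p), 2.0)

  expect_error(partition_sets(om, matrix(1, 3, 3)), "grid")

  # Lambda full / empty degenerate cases
  pf <- partition_sets(om, matrix(1, 2, 2))
  expect_equal(sum(pf$A), 0)
  expect_equal(which(pf$B), which(om == 1))
  expect_equal(partition_ratio(pf), 0.0)
  pe <- partition_sets(om, matrix(0, 2, 2))
  expect_equal(which(pe$A), which(om == 1))
  expect_error(partition_ratio(pe), "empty")
})

test_that("partition invariants hold for every random draw", {
  dom <- build_column_density(24, accel = 3, center_cols = 4, height = 8)
  dla <- build_bernoulli_density(8, 24, accel = 2, center_size = 2,
                                 cap_epsilon = 1e-3)
  for (s in 1:25) {
    om <- sample_mask(dom, rng_seed = s)
    la <- sample_mask(dla, rng_seed = 1000 + s)
    p <- partition_sets(om, la)
    expect_true(!any(p$A & p$B))
    expect_identical(p$A | p$B, om$mask == 1)
  }
})

test_that("mean partition ratio matches (1 - p)/p for uniform half sampling", {
  d <- uniform_dist(100, 100, 0.5)
  rhos <- withr::with_seed(9, replicate(100, {
    partition_ratio(partition_sets(sample_mask(d), sample_mask(d)))
  }))
  expect_equal(mean(rhos), 1.0, tolerance = 0.05)
})

test_that("density estimation recovers the sampler's distribution", {
  # deterministic sampler
  ones <- function() matrix(1, 4, 4)
  expect_true(all(estimate_density(ones, 5)$prob == 1))
  expect_error(estimate_density(ones, 0), "n_draws")

  # Bernoulli(0.3) sampler: ~99% of locations within 3 binomial SEs
  d <- uniform_dist(20, 20, 0.3)
  est <- estimate_density(function() sample_mask(d), 10000, rng_seed = 3)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_gte(mean(abs(est$prob - 0.3) <= 3 * se), 0.98)
  expect_equal(est$structure, "bernoulli_2d")
})
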