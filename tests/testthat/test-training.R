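test_that("zero epochs returns the initialization and an empty history", {
  ds <- toy_ensemble_dataset(4, 2, 2, 0.5, seed = 1)
  est <- diagonal_estimator()
  fit <- train("ssdu_1d", ds, est, epochs = 0, rng_seed = 1,
               lambda_dist = uniform_dist(2, 2, 0.5))
  expect_equal(nrow(fit$history), 0L)
  expect_equal(fit$params, est_init(est, 2, 2))
})

test_that("configuration errors are raised before any training happens", {
  ds <- toy_ensemble_dataset(2, 2, 2, 0.5, seed = 2)
  est <- diagonal_estimator()
  # self-supervised without a partitioning distribution
  expect_error(train("ssdu_1d", ds, est, epochs = 1), "lambda_dist")
  # partitioning density with p = 1 somewhere
  expect_error(train("ssdu_1d", ds, est, epochs = 1,
                     lambda_dist = uniform_dist(2, 2, 1)), "p_tilde < 1")
  # supervised training on a dataset with locked reference access
  expect_error(train("supervised", ds, est, epochs = 1), "disabled")
})

test_that("self-supervised training never touches the reference k-space", {
  # the dataset gate errors on any reference access, so completing a
  # self-supervised run on a locked dataset proves the path is clean
  ds <- toy_ensemble_dataset(6, 2, 2, 0.5, seed = 3)
  expect_false(ds$reference_access)
  fit <- train("unweighted_n2n", ds, diagonal_estimator(), epochs = 2,
               rng_seed = 4, lambda_dist = uniform_dist(2, 2, 0.5))
  expect_equal(nrow(fit$history), 2L)
})

test_that("training is reproducible and redraws the partition mask each epoch", {
  om_dist <- build_column_density(12, accel = 2, center_cols = 2)
  la_dist <- build_column_density(12, accel = 2, center_cols = 2,
                                  cap_epsilon = 1e-3)
  ds <- make_dataset(1, 4, om_dist, rng_seed = 7, n_coils = 1,
                     reference_access = FALSE)
  est <- compact_unrolled_estimator(blocks = 2, kernel_size = 3)
  f1 <- train("ssdu_1d", ds, est, epochs = 3, rng_seed = 11,
              lambda_dist = la_dist)
  f2 <- train("ssdu_1d", ds, est, epochs = 3, rng_seed = 11,
              lambda_dist = la_dist)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-6)
  expect_identical(ssmri:::flatten_params(f1$params),
                   ssmri:::flatten_params(f2$params))

  # per-(epoch, slice) seeds give fresh partition masks across epochs
  # (checked on a half-probability distribution where mask collisions are
  # vanishingly unlikely; the study's near-saturated densities can collide)
  half <- uniform_dist(4, 24, 0.5, structure = "column_1d")
  draws <- lapply(1:3, function(ep)
    sample_mask(half, rng_seed = ssmri:::derive_seed(11, ep, 1))$mask)
  expect_false(identical(draws[[1]], draws[[2]]))
  expect_false(identical(draws[[2]], draws[[3]]))
})

test_that("training converges to the enumerated conditional expectation", {
  # discrete ensemble, deterministic reference = 1, i.i.d. half sampling;
  # a diagonal affine estimator trained with the identity-weighted loss
  # must converge to E[Y | Y~] of the presented ensemble (the acquisition
  # masks are frozen, so the target uses their empirical frequencies; the
  # partition mask is redrawn every epoch, so its density is the nominal one)
  ds <- toy_ensemble_dataset(400, 1, 2, 0.5, seed = 42)
  lam_dist <- uniform_dist(1, 2, 0.5)
  est <- diagonal_estimator()
  f1 <- train("unweighted_n2n", ds, est, epochs = 40, lr = 0.02,
              rng_seed = 7, lambda_dist = lam_dist)
  f2 <- train("unweighted_n2n", ds, est, epochs = 40, lr = 0.002,
              rng_seed = 8, lambda_dist = lam_dist, init_params = f1$params)
  f3 <- train("unweighted_n2n", ds, est, epochs = 30, lr = 3e-4,
              rng_seed = 9, lambda_dist = lam_dist, init_params = f2$params)

  phat <- colMeans(do.call(rbind, lapply(ds$records,
                                         function(r) as.vector(r$omega$mask))))
  sp <- toy_spec(alphabet = 1, p = phat, p_tilde = 0.5, n_cols = 2)
  ce <- conditional_expectations(sp)
  for (g in seq_len(nrow(ce$ytilde))) {
    learned <- Re(f3$params$a * ce$ytilde[g, ] + f3$params$b)
    expect_equal(as.vector(learned), ce$EY[g, ], tolerance = 0.02)
  }
})

test_that("reconstruction routes each method through its inference estimator", {
  sc <- small_scene(h = 16, w = 16, n_coils = 2, accel = 2, seed = 31)
  la_dist <- build_column_density(16, accel = 2, center_cols = 4,
                                  cap_epsilon = 1e-3)
  ds <- make_dataset(1, 3, sc$om_dist, rng_seed = 33, n_coils = 2)
  est <- compact_unrolled_estimator(blocks = 2, kernel_size = 3)
  K <- suppressWarnings(compute_K(sc$om_dist, la_dist))

  fit_ssdu <- train("ssdu_1d", ds, est, epochs = 2, rng_seed = 1,
                    lambda_dist = la_dist)
  fit_n2n <- train("unweighted_n2n", ds, est, epochs = 2, rng_seed = 1,
                   lambda_dist = la_dist, K = K)
  rec <- ds$records[[1]]

  # any dc-mode estimate equals the acquired data on the sampling set
  for (fit in list(fit_ssdu, fit_n2n)) {
    est_dc <- reconstruct(fit, rec$y, rec$omega, rec$sens,
                          input_mode = "tilde", rng_seed = 5)
    on <- which(rep(rec$omega$mask == 1, 2))
    expect_equal(est_dc[on], rec$y$data[on], tolerance = 1e-12)
  }

  # plain SSDU mode is the raw network output on the singly sampled input
  raw <- est_apply(est, fit_ssdu$params, rec$y$data, rec$omega$mask, rec$sens)
  expect_equal(reconstruct(fit_ssdu, rec$y, rec$omega, rec$sens,
                           input_mode = "singly"), raw)

  # unweighted correction with K = 0 leaves the network output unchanged
  K0 <- compute_K(matrix(1, 16, 16), matrix(0.5, 16, 16))
  fit0 <- fit_n2n; fit0$K <- K0
  raw_n2n <- est_apply(est, fit0$params, rec$y$data, rec$omega$mask, rec$sens)
  expect_equal(reconstruct(fit0, rec$y, rec$omega, rec$sens,
                           input_mode = "singly"), raw_n2n)

  # Noisier2Noise inference without K is a configuration error
  fitK <- fit_n2n; fitK$K <- NULL
  expect_error(reconstruct(fitK, rec$y, rec$omega, rec$sens), "K")
})
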