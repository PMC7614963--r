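test_that("toy enumeration is exhaustive with exact probabilities", {
  # N = 2, deterministic reference, i.i.d. binary masks: 1 x 4 x 4 outcomes
  sp <- toy_spec(alphabet = 1, p = 0.5, p_tilde = 0.5, n_cols = 2)
  tab <- enumerate_toy(sp)
  expect_equal(nrow(tab$ytilde), 16L)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  expect_identical(tab$y, tab$omega * tab$y0)
  expect_identical(tab$ytilde, tab$lam * tab$y)

  # column coupling halves the mask degrees of freedom: 2 columns of 2 rows
  spc <- toy_spec(alphabet = 1, p = 0.5, p_tilde = 0.5, n_rows = 2,
                  n_cols = 2, structure = "column")
  mo <- ssmri:::enumerate_masks(spc, spc$p)
  expect_equal(nrow(mo$ind), 4L)  # not 16
  expect_true(all(mo$ind[, 1] == mo$ind[, 2]))
  tabc <- enumerate_toy(spc)
  expect_equal(sum(tabc$prob), 1, tolerance = 1e-12)
})

test_that("conditional expectations match hand-computed values", {
  sp <- toy_spec(alphabet = 1, p = 0.5, p_tilde = 0.5, n_cols = 2)
  ce <- conditional_expectations(sp)
  expect_equal(sum(ce$prob), 1, tolerance = 1e-12)
  i0 <- which(apply(ce$ytilde, 1, function(r) all(r == 0)))
  # P(j in Omega | ytilde_j = 0) = (0.5 * 0.5) / 0.75 = 1/3
  expect_equal(ce$EY[i0, ], c(1, 1) / 3, tolerance = 1e-12)
  expect_equal(ce$EY0[i0, ], c(1, 1), tolerance = 1e-12)

  # p_tilde = 0: the doubly sub-sampled data is always all-zero and the
  # conditional mean is the unconditional one, p_j * E[Y0_j]
  sp0 <- toy_spec(alphabet = c(1, 2), p = c(0.3, 0.7), p_tilde = 0)
  ce0 <- conditional_expectations(sp0)
  expect_equal(nrow(ce0$ytilde), 1L)
  expect_equal(ce0$EY[1, ], c(0.3, 0.7) * 1.5, tolerance = 1e-12)
})

test_that("the de-biasing identity holds exactly on enumerable ensembles", {
  expect_lt(verify_claim1(toy_spec(alphabet = 1, p = 0.5, p_tilde = 0.5,
                                   n_cols = 2)), 1e-12)
  # column-coupled 2 x 2 grid
  expect_lt(verify_claim1(toy_spec(alphabet = c(-1, 1), p = 0.6,
                                   p_tilde = 0.4, n_rows = 2, n_cols = 2,
                                   structure = "column")), 1e-10)
  # uniform densities (scalar correction) satisfy both identities
  spu <- toy_spec(alphabet = c(0.5, 2), p = 0.5, p_tilde = 0.5, n_cols = 3)
  expect_lt(verify_claim1(spu), 1e-10)
  expect_lt(verify_claim2(spu), 1e-10)
})

test_that("the partitioned-loss minimizer is correct where data is unsampled", {
  sp <- toy_spec(alphabet = 1, p = 0.5, p_tilde = 0.5, n_cols = 2)
  ce <- conditional_expectations(sp)
  i0 <- which(apply(ce$ytilde, 1, function(r) all(r == 0)))
  fstar <- ce$EAY[i0, ] / ce$EA[i0, ]
  expect_equal(fstar, c(1, 1), tolerance = 1e-12)  # = E[Y0 | ytilde]
  expect_lt(verify_claim2(sp), 1e-12)

  # nonuniform densities, +/-1 alphabet
  expect_lt(verify_claim2(toy_spec(alphabet = c(-1, 1), p = c(0.9, 0.3),
                                   p_tilde = 0.5)), 1e-10)

  # coordinates observed in ytilde carry no loss-mask mass: the loss set
  # A = Omega \ Lambda excludes them by construction, so they are excluded
  # from the comparison as unconstrained rather than compared
  sampled <- ce$ytilde != 0
  expect_true(all(ce$EA[sampled] == 0))
})

test_that("invalid ensembles are rejected as invalid, not as identity failures", {
  expect_error(toy_spec(alphabet = 1, p = c(0.5, 0), p_tilde = 0.5), "p > 0")
  expect_error(toy_spec(alphabet = 1, p = c(0.5, 0.5), p_tilde = c(0.5, 1)),
               "p_tilde < 1")
  expect_error(toy_spec(alphabet = c(0, 1), p = 0.5, p_tilde = 0.5),
               "exclude 0")
})

test_that("full-rank diagonal weighting does not move the minimizer", {
  sp <- toy_spec(alphabet = c(-1, 2), p = c(0.8, 0.4, 0.6),
                 p_tilde = c(0.3, 0.6, 0.1))
  expect_lt(verify_fullrank_minimizer(sp)$deviation, 1e-10)
  w <- withr::with_seed(4, runif(3, 0.1, 5))
  expect_lt(verify_fullrank_minimizer(sp, w)$deviation, 1e-10)
  # a zero weight leaves that coordinate unconstrained, others unchanged
  res <- verify_fullrank_minimizer(sp, c(1, 0, 2))
  expect_equal(res$unconstrained, 2L)
  expect_lt(res$deviation, 1e-10)
})

test_that("unobserved coordinates are shrunk by exactly the factor K undoes", {
  # with the identity weighting the minimizer is E[Y | Y~]; at coordinates
  # not observed in ytilde it equals (1 - k_j) E[Y0 | Y~] — the shrinkage
  # the (1 - K)^{-1} correction removes at inference
  for (s in 1:5) {
    sp <- random_toy_spec(s)
    ce <- conditional_expectations(sp)
    k <- ssmri:::toy_k(sp)
    for (g in seq_len(nrow(ce$ytilde))) {
      j <- which(ce$ytilde[g, ] == 0)
      if (length(j)) {
        expect_equal(ce$EY[g, j], (1 - k[j]) * ce$EY0[g, j],
                     tolerance = 1e-10)
      }
    }
  }
})
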