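# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# Uniform Bernoulli mask distribution with arbitrary probability (the public
# builders only produce valid acquisition densities, so tests reach for the
# internal constructor for degenerate cases).
uniform_dist <- function(h, w, p, structure = "bernoulli_2d") {
  ssmri:::new_mask_distribution(matrix(p, h, w), structure,
                                center = NULL, cap_epsilon = NULL,
                                target_accel = if (p > 0) 1 / p else Inf)
}

# A tiny multi-coil k-space scene: phantom, coils, reference, mask, data.
small_scene <- function(h = 16, w = 16, n_coils = 2, accel = 2,
                        seed = 123, center_cols = 4) {
  om_dist <- build_column_density(w, accel = accel, center_cols = center_cols,
                                  height = h)
  sens <- make_coils(n_coils, h, w, rng_seed = seed)
  img <- make_phantom(h, w, n_ellipses = 3, rng_seed = seed + 1)
  y0 <- forward_kspace(img, sens)$data
  omega <- sample_mask(om_dist, rng_seed = seed + 2)
  list(h = h, w = w, om_dist = om_dist, sens = sens, img = img, y0 = y0,
       omega = omega, y = ssmri:::bcast_mult(omega$mask, y0))
}

# Discrete-ensemble dataset for convergence tests: deterministic reference
# (all entries = 1), i.i.d. Bernoulli acquisition masks, single flat coil.
toy_ensemble_dataset <- function(n_rec, h, w, p, seed,
                                 reference_access = FALSE) {
  om_dist <- uniform_dist(h, w, p)
  recs <- withr::with_seed(seed, lapply(seq_len(n_rec), function(i) {
    om <- sample_mask(om_dist)
    y0 <- array(1 + 0i, c(h, w, 1))
    list(y = kspace_data(ssmri:::bcast_mult(om$mask, y0), "singly_sub"),
         omega = om, sens = array(1 + 0i, c(h, w, 1)),
         slice_id = i, y0 = kspace_data(y0))
  }))
  structure(list(records = recs, reference_access = reference_access,
                 grid = c(h, w), n_coils = 1, seed = seed,
                 omega_dist = om_dist),
            class = "ss_dataset")
}

rand_karray <- function(h, w, nc, seed = 1) {
  withr::with_seed(seed, array(complex(real = stats::rnorm(h * w * nc),
                                       imaginary = stats::rnorm(h * w * nc)),
                               dim = c(h, w, nc)))
}
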