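#' @section Mask structure types:
#' Two mask families are supported, matching standard Cartesian MRI
#' acquisition:
#' * `"column_1d"` — whole phase-encode columns are acquired or skipped
#'   together; the readout (row) dimension is always fully sampled, so the
#'   per-location probability is constant within each column.
#' * `"bernoulli_2d"` — every k-space location is an independent Bernoulli
#'   draw with its own probability.
#' @name mask-structures
#' @keywords internal
NULL

new_mask_distribution <- function(prob, structure, center, cap_epsilon,
                                  target_accel) {
  structure(
    list(prob = prob, structure = structure, center = center,
         cap_epsilon = cap_epsilon, target_accel = target_accel),
    class = "mask_distribution"
  )
}

#' @export
print.mask_distribution <- function(x, ...) {
  cat(sprintf(
    "mask_distribution: %dx%d %s, R = %.3f (target %.3f)%s\n",
    nrow(x$prob), ncol(x$prob), x$structure,
    length(x$prob) / sum(x$prob), x$target_accel,
    if (!is.null(x$cap_epsilon)) sprintf(", cap 1-%g", x$cap_epsilon) else ""
  ))
  invisible(x)
}

# 0-based index of the center column/row for a grid of size n
# (left-biased for even n, i.e. the floor(n/2) position).
center_index <- function(n) floor(n / 2)

# Columns (1-based) belonging to the centered fully sampled block of size m.
center_block <- function(n, m) {
  if (m <= 0L) return(integer(0))
  c0 <- center_index(n)
  lo <- c0 - floor(m / 2) + (1L - m %% 2L)
  seq.int(lo, lo + m - 1L) + 1L
}

# Scale a clipped density: find s so that sum(pmin(cap, s * base)) +
# center_sum hits target_sum within rtol. Monotone in s, solved by bisection.
scale_density <- function(base, cap, center_sum, target_sum, rtol = 0.005) {
  stopifnot(all(base >= 0))
  lo <- 0
  hi <- if (max(base) > 0) cap / min(base[base > 0]) else 1
  total <- function(s) center_sum + sum(pmin(cap, s * base))
  if (total(hi) < target_sum - 1e-12) {
    # all free locations saturated at the cap and still short of the target
    if (abs(total(hi) - target_sum) / target_sum <= rtol) {
      return(pmin(cap, hi * base))
    }
    stop("requested acceleration is infeasible for this density shape/cap",
         call. = FALSE)
  }
  if (target_sum < center_sum - 1e-12) {
    stop("fully sampled center alone exceeds the sample budget implied by ",
         "the requested acceleration", call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (total(mid) < target_sum) lo <- mid else hi <- mid
    if (abs(total(mid) - target_sum) <= rtol * target_sum / 2) break
  }
  pmin(cap, mid * base)
}

#' Variable-density column-wise sampling distribution
#'
#' Builds the probability density of a 1D (column-wise) Cartesian sampling
#' mask: a fully sampled central block of `center_cols` phase-encode columns
#' and a polynomial decay `(1 - |d|)^order` outside it, where `d` is the
#' column distance from the center normalized to lie strictly inside
#' (-1, 1). The polynomial part is scaled (with clipping at 1, or at
#' `1 - cap_epsilon` when a cap is requested) so that the expected
#' acceleration `width / sum(p)` matches `accel` within 0.5%.
#'
#' The cap is used for the second (partitioning) mask distribution, which
#' must satisfy `p < 1` everywhere for the correction matrix to exist; it is
#' applied to the whole density, which only changes locations that would
#' otherwise reach 1.
#'
#' @param width number of phase-encode columns.
#' @param accel target expected acceleration factor `R >= 1`.
#' @param order polynomial order of the density decay (default 8).
#' @param center_cols number of fully sampled central columns (default 10).
#' @param cap_epsilon if non-`NULL`, probabilities are capped at
#'   `1 - cap_epsilon` everywhere.
#' @param height number of rows in the grid the density is expanded to
#'   (defaults to `width`).
#' @return a `mask_distribution` with an `height x width` probability matrix
#'   constant along columns.
#' @examples
#' d <- build_column_density(64, accel = 4)
#' 64 / sum(d$prob[1, ])  # ~4
#' @export
build_column_density <- function(width, accel, order = 8, center_cols = 10,
                                 cap_epsilon = NULL, height = width) {
  stopifnot(width >= 1, height >= 1, accel >= 1, order >= 0)
  if (center_cols > width) {
    stop("center_cols exceeds grid width", call. = FALSE)
  }
  if (!is.null(cap_epsilon)) stopifnot(cap_epsilon > 0, cap_epsilon < 1)
  cap <- if (is.null(cap_epsilon)) 1 else 1 - cap_epsilon

  cen <- rep(FALSE, width)
  cen[center_block(width, center_cols)] <- TRUE
  c0 <- center_index(width)
  j <- seq_len(width) - 1L
  # strictly |d| < 1 so the polynomial base is positive everywhere
  d <- (j - c0) / (max(c0, width - 1L - c0) + 1L)
  base <- (1 - abs(d))^order
  base[cen] <- 0

  target_sum <- width / accel
  p_col <- numeric(width)
  p_col[cen] <- cap
  if (target_sum >= cap * width - 1e-12) {
    p_col[] <- cap  # R = 1 (or its capped analogue): every column sampled
  } else if (any(!cen)) {
    p_col[!cen] <- scale_density(base[!cen], cap, sum(p_col[cen]), target_sum)
  }
  prob <- matrix(rep(p_col, each = height), nrow = height)
  new_mask_distribution(prob, "column_1d",
                        center = list(cols = center_cols),
                        cap_epsilon = cap_epsilon, target_accel = accel)
}

#' Variable-density 2D Bernoulli sampling distribution
#'
#' Radially symmetric density with a fully sampled `center_size` x
#' `center_size` central region and a polynomial profile outside it, scaled
#' to the target acceleration. With `low_freq_high_prob = TRUE` the density
#' decays with radius, as used for acquisition masks; with `FALSE` it grows
#' with radius, emulating partitioning distributions that keep the loss set
#' concentrated at low frequencies.
#'
#' @param height,width grid size in pixels.
#' @param accel target expected acceleration factor.
#' @param order polynomial order of the radial profile.
#' @param center_size side of the fully sampled central square (default 10).
#' @param cap_epsilon optional cap, as in [build_column_density()].
#' @param low_freq_high_prob if `TRUE` (default) the density is
#'   non-increasing with radius outside the center; if `FALSE`,
#'   non-decreasing.
#' @return a `mask_distribution` with structure `"bernoulli_2d"`.
#' @export
build_bernoulli_density <- function(height, width, accel, order = 8,
                                    center_size = 10, cap_epsilon = NULL,
                                    low_freq_high_prob = TRUE) {
  stopifnot(height >= 1, width >= 1, accel >= 1, order >= 0)
  if (center_size > min(height, width)) {
    stop("center_size exceeds grid dimensions", call. = FALSE)
  }
  if (!is.null(cap_epsilon)) stopifnot(cap_epsilon > 0, cap_epsilon < 1)
  cap <- if (is.null(cap_epsilon)) 1 else 1 - cap_epsilon

  ri <- seq_len(height) - 1L - center_index(height)
  ci <- seq_len(width) - 1L - center_index(width)
  dist <- sqrt(outer(ri^2, ci^2, `+`))
  r <- dist / (max(dist) + 1)  # strictly < 1 everywhere
  base <- if (order == 0) {
    matrix(1, height, width)
  } else if (low_freq_high_prob) {
    (1 - r)^order
  } else {
    1 - (1 - r)^order
  }

  cen <- matrix(FALSE, height, width)
  cen[center_block(height, center_size), center_block(width, center_size)] <- TRUE
  base[cen] <- 0

  target_sum <- height * width / accel
  prob <- matrix(0, height, width)
  prob[cen] <- cap
  if (target_sum >= cap * height * width - 1e-12) {
    prob[] <- cap
  } else if (any(!cen)) {
    prob[!cen] <- scale_density(base[!cen], cap, sum(prob[cen]), target_sum)
  }
  new_mask_distribution(prob, "bernoulli_2d",
                        center = list(size = center_size),
                        cap_epsilon = cap_epsilon, target_accel = accel)
}

new_kspace_mask <- function(mask, structure) {
  structure(list(mask = mask, structure = structure), class = "kspace_mask")
}

#' @export
print.kspace_mask <- function(x, ...) {
  cat(sprintf("kspace_mask: %dx%d %s, %d/%d sampled\n",
              nrow(x$mask), ncol(x$mask), x$structure,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

# Accept kspace_mask or bare 0/1 matrix.
as_mask_matrix <- function(m) {
  if (inherits(m, "kspace_mask")) m <- m$mask
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  m
}

#' Draw a binary sampling mask from a distribution
#'
#' For `"bernoulli_2d"` distributions every location is an independent
#' Bernoulli draw; for `"column_1d"` each column is a single Bernoulli draw
#' replicated down the rows (readout direction fully coupled).
#'
#' @param dist a [mask_distribution][build_column_density].
#' @param rng_seed optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is untouched.
#' @return a `kspace_mask`.
#' @export
sample_mask <- function(dist, rng_seed = NULL) {
  stopifnot(inherits(dist, "mask_distribution"))
  draw <- function() {
    h <- nrow(dist$prob); w <- ncol(dist$prob)
    if (dist$structure == "column_1d") {
      cols <- as.numeric(stats::runif(w) < dist$prob[1, ])
      matrix(rep(cols, each = h), nrow = h)
    } else {
      matrix(as.numeric(stats::runif(h * w) < dist$prob), h, w)
    }
  }
  m <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  new_kspace_mask(m, dist$structure)
}

#' Partition an acquired sampling set by a second mask
#'
#' Splits the acquired set into the loss set `A = Omega \ Lambda` and the
#' input set `B = Omega intersect Lambda`. By construction `A` and `B` are
#' disjoint and their union is the acquired set.
#'
#' @param omega acquisition mask (`kspace_mask` or 0/1 matrix).
#' @param lam partitioning mask on the same grid.
#' @return an object of class `mask_partition` with logical matrices `A`,
#'   `B`.
#' @export
partition_sets <- function(omega, lam) {
  mo <- as_mask_matrix(omega)
  ml <- as_mask_matrix(lam)
  if (!all(dim(mo) == dim(ml))) {
    stop("omega and lambda masks have different grid sizes", call. = FALSE)
  }
  structure(list(A = mo == 1 & ml == 0, B = mo == 1 & ml == 1),
            class = "mask_partition")
}

#' Loss-to-input set size ratio of a partition
#'
#' Returns `|A| / |B|`, the ratio commonly used to parameterize sampling-set
#' partitions.
#'
#' @param p a `mask_partition` from [partition_sets()].
#' @return a single non-negative number.
#' @export
partition_ratio <- function(p) {
  stopifnot(inherits(p, "mask_partition"))
  nb <- sum(p$B)
  if (nb == 0) stop("partition has an empty input set B", call. = FALSE)
  sum(p$A) / nb
}

#' Monte-Carlo density estimate of a procedural mask sampler
#'
#' Averages `n_draws` indicator draws from `sampler` to estimate its
#' per-location sampling density. This is how a closed-form density is
#' obtained for procedural partitioners that are defined only as code.
#'
#' @param sampler a function of no arguments returning a `kspace_mask` (or
#'   0/1 matrix) on a fixed grid.
#' @param n_draws number of draws to average (>= 1).
#' @param rng_seed optional integer seed for the whole estimation.
#' @return a `mask_distribution` whose `prob` is the empirical mean
#'   indicator; tagged with the sampler's structure when it declares one,
#'   `"bernoulli_2d"` otherwise.
#' @export
estimate_density <- function(sampler, n_draws, rng_seed = NULL) {
  if (n_draws < 1) stop("n_draws must be at least 1", call. = FALSE)
  run <- function() {
    first <- sampler()
    str <- if (inherits(first, "kspace_mask")) first$structure else "bernoulli_2d"
    acc <- as_mask_matrix(first)
    if (n_draws > 1) {
      for (i in seq_len(n_draws - 1)) acc <- acc + as_mask_matrix(sampler())
    }
    list(prob = acc / n_draws, structure = str)
  }
  est <- if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
  new_mask_distribution(est$prob, est$structure, center = NULL,
                        cap_epsilon = NULL,
                        target_accel = length(est$prob) / sum(est$prob))
}
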