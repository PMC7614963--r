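#' Diagonal correction matrix from a pair of sampling densities
#'
#' For an acquisition density `p` and a partitioning density `pt` the
#' per-location correction entry is
#' \deqn{k_j = (1 - p_j) / (1 - \tilde p_j p_j),}
#' the diagonal of the matrix that de-biases a network trained to map
#' doubly sub-sampled k-space to singly sub-sampled k-space. The derived
#' weights `(1 - k_j)^{-1}` (inference correction) and `(1 - k_j)^{-1/2}`
#' (loss weighting) are returned alongside. An equivalent probabilistic
#' form, used as a cross-check in the tests, is
#' `(1 - k_j)^{-1} = P(j not in Lambda & Omega) / P(j in Omega \ Lambda)`.
#'
#' Requires `p_j > 0` and `pt_j < 1` everywhere so that `1 - k_j > 0`.
#'
#' @param omega_dist acquisition-mask density (`mask_distribution`).
#' @param lambda_dist partitioning-mask density on the same grid.
#' @param max_weight cap on `(1 - k)^{-1}`; values above it are clipped with
#'   a warning, guarding against `pt -> 1` blow-up.
#' @return an object of class `k_matrix` with matrices `k`, `w1` and
#'   `w_half`.
#' @examples
#' om <- build_column_density(32, accel = 2)
#' la <- build_column_density(32, accel = 2, cap_epsilon = 1e-3)
#' K <- compute_K(om, la)
#' range(K$k)
#' @export
compute_K <- function(omega_dist, lambda_dist, max_weight = 1e6) {
  p <- if (inherits(omega_dist, "mask_distribution")) omega_dist$prob else omega_dist
  pt <- if (inherits(lambda_dist, "mask_distribution")) lambda_dist$prob else lambda_dist
  if (!all(dim(p) == dim(pt))) {
    stop("density grids have different sizes", call. = FALSE)
  }
  bad_p <- which(p <= 0)
  bad_pt <- which(pt >= 1)
  if (length(bad_p) || length(bad_pt)) {
    stop(sprintf(
      paste0("correction matrix undefined: need p > 0 and p-tilde < 1 ",
             "everywhere (%d locations with p = 0, first: %s; %d with ",
             "p-tilde = 1, first: %s)"),
      length(bad_p), paste(utils::head(bad_p, 3), collapse = ","),
      length(bad_pt), paste(utils::head(bad_pt, 3), collapse = ",")
    ), call. = FALSE)
  }
  k <- (1 - p) / (1 - pt * p)
  w1 <- 1 / (1 - k)
  if (any(w1 > max_weight)) {
    warning(sprintf("clipping %d correction weights above %g",
                    sum(w1 > max_weight), max_weight))
    w1 <- pmin(w1, max_weight)
  }
  structure(list(k = k, w1 = w1, w_half = sqrt(w1)), class = "k_matrix")
}

#' @export
print.k_matrix <- function(x, ...) {
  q <- function(m) stats::quantile(m, c(0, 0.5, 1))
  cat("k_matrix (min / median / max):\n")
  cat(sprintf("  k:      %.4g / %.4g / %.4g\n", q(x$k)[1], q(x$k)[2], q(x$k)[3]))
  cat(sprintf("  w1:     %.4g / %.4g / %.4g\n", q(x$w1)[1], q(x$w1)[2], q(x$w1)[3]))
  cat(sprintf("  w_half: %.4g / %.4g / %.4g\n",
              q(x$w_half)[1], q(x$w_half)[2], q(x$w_half)[3]))
  invisible(x)
}

as_kmat <- function(K) {
  stopifnot(inherits(K, "k_matrix"))
  K
}

#' Noisier2Noise inference estimators
#'
#' `n2n_correct_plain()` applies the de-biasing correction
#' `(1 - K)^{-1} (f - K y)` to a network output `f` obtained from input
#' `y`. `n2n_correct_dc()` forms the data-consistent estimate
#' `(1 - M_Omega)(1 - K)^{-1} f + y`, which equals the acquired data `y`
#' exactly at every sampled location and applies the correction only to the
#' unsampled remainder (used when the network input was the doubly
#' sub-sampled data).
#'
#' @param f_out network output, complex `(H, W, C)` array (or matrix).
#' @param y_in,y acquired (singly sub-sampled) k-space, same shape.
#' @param omega acquisition mask.
#' @param K a [k_matrix][compute_K].
#' @return complex array of the same shape as `f_out`.
#' @export
n2n_correct_plain <- function(f_out, y_in, K) {
  f <- as_karray(f_out); y <- as_karray(y_in); K <- as_kmat(K)
  stopifnot(all(dim(f) == dim(y)), all(dim(K$k) == dim(f)[1:2]))
  bcast_mult(K$w1, f - bcast_mult(K$k, y))
}

#' @rdname n2n_correct_plain
#' @export
n2n_correct_dc <- function(f_out, y, omega, K) {
  f <- as_karray(f_out); yy <- as_karray(y); K <- as_kmat(K)
  m <- as_mask_matrix(omega)
  stopifnot(all(dim(f) == dim(yy)), all(dim(m) == dim(f)[1:2]))
  bcast_mult((1 - m) * K$w1, f) + yy
}

#' SSDU inference estimators
#'
#' With `mode = "dc_tilde_input"` the network output `f` (computed from the
#' doubly sub-sampled input) is overwritten with the acquired data on the
#' sampling set: `(1 - M_Omega) f + y`. With `mode = "plain_y_input"` the
#' raw network output on the singly sub-sampled input is the estimate. No
#' correction matrix is needed in either case — removing it is precisely
#' what the SSDU loss masking buys.
#'
#' @param f_out network output, complex `(H, W, C)` array.
#' @param y acquired k-space, same shape.
#' @param omega acquisition mask.
#' @param mode `"dc_tilde_input"` or `"plain_y_input"`.
#' @return complex array of the same shape as `f_out`.
#' @export
ssdu_estimate <- function(f_out, y, omega,
                          mode = c("dc_tilde_input", "plain_y_input")) {
  mode <- match.arg(mode)
  f <- as_karray(f_out)
  if (mode == "plain_y_input") return(f)
  yy <- as_karray(y)
  m <- as_mask_matrix(omega)
  stopifnot(all(dim(f) == dim(yy)), all(dim(m) == dim(f)[1:2]))
  bcast_mult(1 - m, f) + yy
}
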