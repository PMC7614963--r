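#' Centered unitary 2D Fourier transforms
#'
#' The package fixes a single Fourier convention repo-wide: transforms are
#' orthonormal (unitary), so Parseval's identity holds exactly and the
#' normalized mean squared error is identical in k-space and in the coil
#' image domain. The zero frequency sits at the center of the grid
#' (`floor(n/2) + 1` in 1-based indexing), matching the convention used for
#' the sampling densities, whose fully sampled region is defined around the
#' k-space center.
#'
#' @param x complex matrix (image for `ft2`, k-space for `ift2`).
#' @return complex matrix of the same dimension.
#' @examples
#' x <- matrix(complex(real = rnorm(16)), 4, 4)
#' max(Mod(ift2(ft2(x)) - x)) < 1e-12
#' @export
ft2 <- function(x) {
  fftshift(stats::fft(ifftshift(x))) / sqrt(length(x))
}

#' @rdname ft2
#' @export
ift2 <- function(x) {
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))
}

#' Swap quadrants so the zero-frequency bin moves to the grid center
#'
#' `fftshift` moves element (1,1) to (floor(h/2)+1, floor(w/2)+1);
#' `ifftshift` is its exact inverse (they differ for odd sizes).
#'
#' @param x matrix.
#' @return matrix with quadrants swapped.
#' @export
fftshift <- function(x) {
  roll2(x, floor(nrow(x) / 2), floor(ncol(x) / 2))
}

#' @rdname fftshift
#' @export
ifftshift <- function(x) {
  roll2(x, ceiling(nrow(x) / 2), ceiling(ncol(x) / 2))
}

# Circular roll of a matrix by (kr, kc) toward higher indices.
roll2 <- function(x, kr, kc) {
  h <- nrow(x); w <- ncol(x)
  ri <- ((seq_len(h) - 1L - kr) %% h) + 1L
  ci <- ((seq_len(w) - 1L - kc) %% w) + 1L
  x[ri, ci, drop = FALSE]
}

# Per-coil centered unitary FFT of an (H, W, C) complex array.
ft2_coils <- function(x) {
  out <- x
  for (cc in seq_len(dim(x)[3])) out[, , cc] <- ft2(x[, , cc])
  out
}

ift2_coils <- function(x) {
  out <- x
  for (cc in seq_len(dim(x)[3])) out[, , cc] <- ift2(x[, , cc])
  out
}

# Coerce a kspace_data wrapper or bare array/matrix to an (H, W, C) array.
as_karray <- function(y) {
  if (inherits(y, "kspace_data")) y <- y$data
  if (is.matrix(y)) dim(y) <- c(dim(y), 1L)
  stopifnot(length(dim(y)) == 3L)
  if (!is.complex(y)) storage.mode(y) <- "complex"
  y
}

# Multiply an (H, W, C) array by an (H, W) real/binary weight, broadcasting
# across coils.
bcast_mult <- function(w, y) {
  array(as.vector(w) * matrix(y, nrow = length(w)), dim = dim(y))
}
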