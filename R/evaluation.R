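#' Normalized mean squared error in k-space
#'
#' `||estimate - reference||^2 / ||reference||^2` over all coils and
#' locations. Scale-aware, not scale-invariant: `nmse(a*y0, y0) = (a-1)^2`.
#' Under the package's unitary Fourier convention this equals the NMSE of
#' the coil images.
#'
#' @param estimate,reference complex `(H, W, C)` arrays (or `kspace_data`).
#' @return single non-negative number.
#' @export
nmse <- function(estimate, reference) {
  e <- as_karray(estimate); r <- as_karray(reference)
  stopifnot(all(dim(e) == dim(r)))
  den <- sum(Mod(r)^2)
  if (den == 0) stop("reference has zero energy", call. = FALSE)
  sum(Mod(e - r)^2) / den
}

#' Root-sum-of-squares image from multi-coil k-space
#'
#' Inverse-transforms each coil and combines magnitudes as
#' `sqrt(sum_c |F^H y_c|^2)`, then crops the central `crop x crop` region
#' when it fits the grid (cropping is skipped with a warning on smaller
#' grids, as is the case for synthetic phantoms).
#'
#' @param y complex `(H, W, C)` k-space.
#' @param crop side of the central crop in pixels (default 320).
#' @return real matrix.
#' @export
rss_image <- function(y, crop = 320) {
  yy <- as_karray(y)
  h <- dim(yy)[1]; w <- dim(yy)[2]
  acc <- matrix(0, h, w)
  for (cc in seq_len(dim(yy)[3])) acc <- acc + Mod(ift2(yy[, , cc]))^2
  img <- sqrt(acc)
  if (!is.null(crop)) {
    if (crop > h || crop > w) {
      warning(sprintf("crop %d exceeds grid %dx%d; returning uncropped image",
                      crop, h, w))
    } else {
      r0 <- center_index(h) - floor(crop / 2) + (1 - crop %% 2)
      c0 <- center_index(w) - floor(crop / 2) + (1 - crop %% 2)
      img <- img[r0 + seq_len(crop), c0 + seq_len(crop)]
    }
  }
  img
}

# Mean over every full win x win window ("valid" uniform filter), via a
# summed-area table.
win_mean <- function(x, win) {
  sat <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  sat <- t(sat)
  pad <- rbind(0, cbind(0, sat))
  h <- nrow(x); w <- ncol(x)
  i <- seq_len(h - win + 1); j <- seq_len(w - win + 1)
  (pad[i + win, j + win, drop = FALSE] - pad[i, j + win, drop = FALSE] -
     pad[i + win, j, drop = FALSE] + pad[i, j, drop = FALSE]) / win^2
}

#' Structural similarity index of two magnitude images
#'
#' Standard single-scale SSIM with a uniform `win_size` window,
#' regularization constants `K1 = 0.01`, `K2 = 0.03`, sample (unbiased)
#' local covariances, and the data range taken from the reference image —
#' the convention commonly used for MRI reconstruction benchmarks. The
#' SSIM map is averaged over all fully interior windows.
#'
#' @param estimate_image,reference_image real matrices of equal size.
#' @param data_range dynamic range `L`; defaults to
#'   `max(reference) - min(reference)`.
#' @param win_size window side (odd, default 7).
#' @return single number in `[-1, 1]`.
#' @export
ssim <- function(estimate_image, reference_image, data_range = NULL,
                 win_size = 7) {
  x <- estimate_image; y <- reference_image
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            win_size %% 2 == 1, all(dim(x) >= win_size))
  if (is.null(data_range)) data_range <- max(y) - min(y)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  np <- win_size^2
  cov_norm <- np / (np - 1)

  ux <- win_mean(x, win_size)
  uy <- win_mean(y, win_size)
  uxx <- win_mean(x * x, win_size)
  uyy <- win_mean(y * y, win_size)
  uxy <- win_mean(x * y, win_size)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)

  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}
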