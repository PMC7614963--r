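#' Multi-coil k-space container
#'
#' A light wrapper for a complex `(H, W, C)` k-space array with a role tag
#' recording where it sits in the measurement chain: `"full"` (reference
#' `y0`), `"singly_sub"` (`y = M_Omega y0`) or `"doubly_sub"`
#' (`y_tilde = M_Lambda M_Omega y0`). Most numerical functions in the
#' package accept either this wrapper or a bare complex array.
#'
#' @param data complex `(H, W, C)` array (a matrix is treated as one coil).
#' @param role one of `"full"`, `"singly_sub"`, `"doubly_sub"`.
#' @return an object of class `kspace_data`.
#' @export
kspace_data <- function(data, role = c("full", "singly_sub", "doubly_sub")) {
  role <- match.arg(role)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  structure(list(data = data, role = role), class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("kspace_data [%s]: %dx%d, %d coil(s)\n", x$role, d[1], d[2], d[3]))
  invisible(x)
}

# Smooth an image by multiplying its centered spectrum with a Gaussian.
gaussian_blur <- function(img, sigma) {
  h <- nrow(img); w <- ncol(img)
  fy <- (seq_len(h) - 1 - center_index(h)) / h
  fx <- (seq_len(w) - 1 - center_index(w)) / w
  filt <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  ift2(ft2(img) * filt)
}

#' Random smooth complex phantom
#'
#' Generates a complex test image with the structure the sampling model
#' assumes: magnitude formed by random ellipses on a smooth elliptical
#' background, lightly blurred so the spectrum is concentrated at low
#' spatial frequencies, and a smooth phase given by a random low-order 2D
#' polynomial. Deterministic for a given seed.
#'
#' @param height,width image size in pixels.
#' @param n_ellipses number of random ellipses (0 gives background only).
#' @param rng_seed integer seed.
#' @param blur_sigma Gaussian blur width in pixels applied to the magnitude.
#' @return complex `height x width` matrix.
#' @export
make_phantom <- function(height, width, n_ellipses = 8, rng_seed = 1,
                         blur_sigma = 1.5) {
  stopifnot(height >= 4, width >= 4, n_ellipses >= 0)
  withr::with_seed(rng_seed, {
    u <- (seq_len(height) - 1 - center_index(height)) / (height / 2)
    v <- (seq_len(width) - 1 - center_index(width)) / (width / 2)
    U <- matrix(u, height, width)
    V <- matrix(v, height, width, byrow = TRUE)
    mag <- 0.5 * exp(-(U^2 + V^2) / 0.9)  # smooth background
    mag <- mag + as.numeric(U^2 / 0.8^2 + V^2 / 0.75^2 <= 1) * 0.3
    for (i in seq_len(n_ellipses)) {
      cu <- stats::runif(1, -0.5, 0.5); cv <- stats::runif(1, -0.5, 0.5)
      a <- stats::runif(1, 0.08, 0.35); b <- stats::runif(1, 0.08, 0.35)
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 0.2, 0.9) * sample(c(-1, 1), 1)
      du <- (U - cu) * cos(th) + (V - cv) * sin(th)
      dv <- -(U - cu) * sin(th) + (V - cv) * cos(th)
      mag <- mag + amp * as.numeric(du^2 / a^2 + dv^2 / b^2 <= 1)
    }
    mag <- Re(gaussian_blur(mag, blur_sigma))
    coef <- stats::runif(6, -1, 1)
    phase <- coef[1] + coef[2] * U + coef[3] * V + coef[4] * U * V +
      coef[5] * U^2 + coef[6] * V^2
    mag * exp(1i * pi * phase / 2)
  })
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian-lobed magnitudes centered on a ring around the field of view
#' with smooth random linear phases, normalized so that
#' `sum_c |S_c|^2 = 1` at every pixel (so root-sum-of-squares coil
#' combination is unit-gain). With one coil the magnitude is identically 1.
#'
#' @param n_coils number of receiver coils.
#' @param height,width map size in pixels.
#' @param rng_seed integer seed.
#' @return complex `(height, width, n_coils)` array.
#' @export
make_coils <- function(n_coils, height, width, rng_seed = 1) {
  stopifnot(n_coils >= 1)
  withr::with_seed(rng_seed, {
    u <- (seq_len(height) - 1 - center_index(height)) / (height / 2)
    v <- (seq_len(width) - 1 - center_index(width)) / (width / 2)
    U <- matrix(u, height, width)
    V <- matrix(v, height, width, byrow = TRUE)
    S <- array(complex(real = 0, imaginary = 0),
               dim = c(height, width, n_coils))
    for (cc in seq_len(n_coils)) {
      ang <- 2 * pi * (cc - 1) / n_coils + stats::runif(1, -0.2, 0.2)
      cu <- 0.9 * cos(ang); cv <- 0.9 * sin(ang)
      mag <- 0.15 + exp(-((U - cu)^2 + (V - cv)^2) / 0.8)
      slope <- stats::runif(2, -0.5, 0.5)
      S[, , cc] <- mag * exp(1i * pi * (slope[1] * U + slope[2] * V))
    }
    norm <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
    for (cc in seq_len(n_coils)) S[, , cc] <- S[, , cc] / norm
    S
  })
}

#' Forward model: image to fully sampled multi-coil k-space
#'
#' Applies the coil sensitivities and the centered unitary 2D Fourier
#' transform per coil. Under this convention Parseval's identity holds:
#' the k-space energy equals the summed coil-image energy.
#'
#' @param image complex `height x width` image.
#' @param coils complex `(height, width, C)` sensitivity array.
#' @return a [kspace_data] with role `"full"`.
#' @export
forward_kspace <- function(image, coils) {
  S <- as_karray(coils)
  stopifnot(all(dim(S)[1:2] == dim(image)))
  out <- array(complex(real = 0, imaginary = 0), dim = dim(S))
  for (cc in seq_len(dim(S)[3])) out[, , cc] <- ft2(S[, , cc] * image)
  kspace_data(out, "full")
}

#' Seeded synthetic training dataset
#'
#' Generates `n_volumes * slices_per_volume` slices of multi-coil k-space
#' from random phantoms, draws one acquisition mask per slice from
#' `omega_dist` and freezes it (the acquisition mask of a prospectively
#' sub-sampled scan never changes between epochs), and stores the acquired
#' data `y = M_Omega y0`. The fully sampled reference is retained for
#' evaluation but gated behind [get_reference()]: with
#' `reference_access = FALSE` any attempt to read it errors, which is how
#' self-supervised runs guarantee they never touch ground truth.
#'
#' @param n_volumes,slices_per_volume dataset size; coil maps are shared
#'   within a volume.
#' @param omega_dist acquisition-mask distribution
#'   ([build_column_density()] / [build_bernoulli_density()]).
#' @param rng_seed master seed; all phantom, coil and mask seeds derive
#'   from it, so regeneration is bit-identical.
#' @param n_coils receiver coils per volume.
#' @param n_ellipses passed to [make_phantom()].
#' @param reference_access whether [get_reference()] may return `y0`.
#' @return an object of class `ss_dataset`: a list of records, each with
#'   elements `y` (`kspace_data`, singly sub-sampled), `omega`
#'   (`kspace_mask`), `sens`, and `slice_id`.
#' @export
make_dataset <- function(n_volumes, slices_per_volume, omega_dist,
                         rng_seed = 1, n_coils = 4, n_ellipses = 8,
                         reference_access = TRUE) {
  stopifnot(inherits(omega_dist, "mask_distribution"))
  h <- nrow(omega_dist$prob); w <- ncol(omega_dist$prob)
  records <- list()
  sid <- 0L
  for (vol in seq_len(n_volumes)) {
    coil_seed <- derive_seed(rng_seed, 1L, vol)
    sens <- make_coils(n_coils, h, w, rng_seed = coil_seed)
    for (sl in seq_len(slices_per_volume)) {
      sid <- sid + 1L
      ph_seed <- derive_seed(rng_seed, 2L, sid)
      om_seed <- derive_seed(rng_seed, 3L, sid)
      img <- make_phantom(h, w, n_ellipses = n_ellipses, rng_seed = ph_seed)
      y0 <- forward_kspace(img, sens)
      omega <- sample_mask(omega_dist, rng_seed = om_seed)
      y <- kspace_data(bcast_mult(omega$mask, y0$data), "singly_sub")
      records[[sid]] <- list(y = y, omega = omega, sens = sens,
                             slice_id = sid, y0 = y0)
    }
  }
  structure(list(records = records, reference_access = reference_access,
                 grid = c(h, w), n_coils = n_coils, seed = rng_seed,
                 omega_dist = omega_dist),
            class = "ss_dataset")
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat(sprintf("ss_dataset: %d slices, %dx%d, %d coils, reference %s\n",
              length(x$records), x$grid[1], x$grid[2], x$n_coils,
              if (x$reference_access) "accessible" else "locked"))
  invisible(x)
}

#' @export
length.ss_dataset <- function(x) length(x$records)

#' Access the fully sampled reference of a dataset record
#'
#' Errors when the dataset was built with `reference_access = FALSE`; this
#' is the guard that keeps self-supervised training paths honest.
#'
#' @param dataset an `ss_dataset`.
#' @param i record index.
#' @return a [kspace_data] with role `"full"`.
#' @export
get_reference <- function(dataset, i) {
  stopifnot(inherits(dataset, "ss_dataset"))
  if (!isTRUE(dataset$reference_access)) {
    stop("reference k-space access is disabled for this dataset ",
         "(built with reference_access = FALSE)", call. = FALSE)
  }
  dataset$records[[i]]$y0
}

# Mix a master seed with a stream tag and an index into a 31-bit seed.
derive_seed <- function(master, stream, index) {
  as.integer((as.double(master) * 1000003 + stream * 7919 + index * 104729)
             %% 2147483629)
}
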