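#' Data-consistent network wrapper
#'
#' Given a raw network output `g_out` and the (doubly sub-sampled) input
#' data `y_tilde`, returns `(1 - M) g_out + y_tilde` where `M` is the
#' combined input mask (elementwise product of acquisition and partitioning
#' masks). The output equals the input data exactly at every input-sampled
#' location, so the network only has to learn the unsampled remainder, and
#' any loss decomposition that assumes input-consistency holds by
#' construction.
#'
#' @param g_out raw network output, complex `(H, W, C)` array.
#' @param y_tilde network input data, same shape (zero off the mask).
#' @param combined_mask the input sampling mask `M_Lambda * M_Omega`.
#' @return complex array of the same shape.
#' @export
dc_wrap <- function(g_out, y_tilde, combined_mask) {
  g <- as_karray(g_out); yt <- as_karray(y_tilde)
  m <- as_mask_matrix(combined_mask)
  stopifnot(all(dim(g) == dim(yt)), all(dim(m) == dim(g)[1:2]))
  bcast_mult(1 - m, g) + yt
}

#' Restrict k-space to a support region
#'
#' Zeroes the estimate outside `support`, the indicator of valid
#' (non-zero-padded) k-space. Identity when the support is full.
#'
#' @param f_out complex `(H, W, C)` array.
#' @param support binary `H x W` support indicator.
#' @return complex array of the same shape.
#' @export
apply_support <- function(f_out, support) {
  f <- as_karray(f_out)
  s <- as_mask_matrix(support)
  stopifnot(all(dim(s) == dim(f)[1:2]))
  bcast_mult(s, f)
}

# ---------------------------------------------------------------------------
# Estimator contract: an S3 object with methods
#   est_init(est, h, w)                            -> params (named list)
#   est_apply(est, params, y_in, mask, sens)       -> (H, W, C) output
#   est_value_grad(est, params, y_in, mask, sens, target, weight2)
#                                                  -> list(loss, grads)
# `grads` mirrors the structure of `params`; complex gradients follow the
# convention dL/dRe(w) = 2 Re(grad), dL/dIm(w) = 2 Im(grad).
# ---------------------------------------------------------------------------

#' Apply a reconstruction estimator
#'
#' Generic entry points of the estimator contract: `est_init()` creates the
#' trainable parameters for a grid, `est_apply()` runs the estimator on
#' input k-space, and `est_value_grad()` returns the weighted squared-error
#' loss against a target together with the analytic parameter gradients.
#'
#' @param est an estimator object ([compact_unrolled_estimator()] or
#'   [diagonal_estimator()]).
#' @param params parameter list from `est_init()` (or updated by training).
#' @param y_in input k-space, complex `(H, W, C)` array.
#' @param mask the sampling mask of the input data.
#' @param sens coil sensitivities `(H, W, C)` (ignored by estimators that
#'   do not use them).
#' @param h,w grid size.
#' @param target,weight2 regression target and squared per-location loss
#'   weight (`NULL` for identity) used by `est_value_grad()`.
#' @return `est_apply()` returns a complex `(H, W, C)` array;
#'   `est_value_grad()` a list with elements `loss` and `grads`.
#' @export
est_apply <- function(est, params, y_in, mask, sens = NULL) {
  UseMethod("est_apply")
}

#' @rdname est_apply
#' @export
est_init <- function(est, h, w) UseMethod("est_init")

#' @rdname est_apply
#' @export
est_value_grad <- function(est, params, y_in, mask, sens = NULL,
                           target, weight2 = NULL) {
  UseMethod("est_value_grad")
}

# --- compact unrolled estimator --------------------------------------------

#' Compact unrolled data-consistency estimator
#'
#' A small physics-guided reconstruction network: `blocks` repetitions of
#' (a) inverse Fourier transform and coil combination with the provided
#' sensitivities, (b) a learned residual refinement in the image domain
#' (a complex convolution kernel, applied circularly via the FFT), and
#' (c) a soft data-consistency step in k-space with a learnable step size
#' per block, pulling the estimate toward the masked input data. The
#' refinement kernels are zero-initialized and the step sizes start at 1,
#' so the untrained estimator reduces to projecting the input onto the coil
#' subspace and restoring the acquired samples exactly — with flat
#' single-coil sensitivities, the identity on its input.
#'
#' The estimator is deterministic given parameters and input, and linear in
#' the data for fixed parameters. Gradients of the weighted squared-error
#' loss are computed analytically by adjoint passes through the same
#' operators.
#'
#' @param blocks number of unrolled blocks (default 4).
#' @param kernel_size side of the square refinement kernel (odd, default 5).
#' @return an estimator object usable with [est_init()], [est_apply()] and
#'   [est_value_grad()]; its `n_params` field reports the real parameter
#'   count once initialized.
#' @export
compact_unrolled_estimator <- function(blocks = 4, kernel_size = 5) {
  stopifnot(blocks >= 1, kernel_size >= 1, kernel_size %% 2 == 1)
  structure(list(blocks = blocks, kernel_size = kernel_size),
            class = c("unrolled_estimator", "kspace_estimator"))
}

#' @export
print.unrolled_estimator <- function(x, ...) {
  n_par <- x$blocks * (2 * x$kernel_size^2 + 1)
  cat(sprintf(
    "compact unrolled estimator: %d block(s), %dx%d complex kernels + 1 dc step size each (%d real parameters)\n",
    x$blocks, x$kernel_size, x$kernel_size, n_par))
  invisible(x)
}

#' @export
print.diagonal_estimator <- function(x, ...) {
  cat("diagonal affine k-space estimator (per-location complex gain + offset)\n")
  invisible(x)
}

#' @export
est_init.unrolled_estimator <- function(est, h, w) {
  ks <- est$kernel_size
  stopifnot(ks <= h, ks <= w)
  kernels <- replicate(est$blocks,
                       matrix(complex(real = 0, imaginary = 0), ks, ks),
                       simplify = FALSE)
  list(kernels = kernels, eta = rep(1, est$blocks))
}

# Embed a kernel in an H x W matrix centered (circularly) at index (1, 1),
# so that FFT-domain multiplication realizes an unshifted convolution.
embed_kernel <- function(w, h, wd) {
  ks <- nrow(w); r <- (ks - 1L) %/% 2L
  pad <- matrix(complex(real = 0, imaginary = 0), h, wd)
  ri <- ((seq_len(ks) - 1L - r) %% h) + 1L
  ci <- ((seq_len(ks) - 1L - r) %% wd) + 1L
  pad[ri, ci] <- w
  pad
}

extract_kernel <- function(pad, ks) {
  h <- nrow(pad); wd <- ncol(pad); r <- (ks - 1L) %/% 2L
  ri <- ((seq_len(ks) - 1L - r) %% h) + 1L
  ci <- ((seq_len(ks) - 1L - r) %% wd) + 1L
  pad[ri, ci]
}

# Coil combine Sum_c conj(S_c) . IFT(k_c) and its adjoint.
coil_combine <- function(k, sens) {
  x <- matrix(complex(real = 0, imaginary = 0), dim(k)[1], dim(k)[2])
  for (cc in seq_len(dim(k)[3])) x <- x + Conj(sens[, , cc]) * ift2(k[, , cc])
  x
}

coil_expand <- function(x, sens) {
  out <- array(complex(real = 0, imaginary = 0), dim = dim(sens))
  for (cc in seq_len(dim(sens)[3])) out[, , cc] <- ft2(sens[, , cc] * x)
  out
}

unrolled_forward <- function(est, params, y_in, m, sens, keep_cache = FALSE) {
  h <- dim(y_in)[1]; wd <- dim(y_in)[2]
  n <- h * wd
  k <- y_in
  cache <- if (keep_cache) vector("list", est$blocks)
  for (b in seq_len(est$blocks)) {
    x <- coil_combine(k, sens)
    Ux <- stats::fft(x) / sqrt(n)
    Wf <- stats::fft(embed_kernel(params$kernels[[b]], h, wd))
    x2 <- x + stats::fft(Ux * Wf, inverse = TRUE) / sqrt(n)
    kp <- coil_expand(x2, sens)
    k <- kp - params$eta[b] * bcast_mult(m, kp - y_in)
    if (keep_cache) cache[[b]] <- list(Ux = Ux, Wf = Wf, kp = kp)
  }
  list(f = k, cache = cache)
}

#' @export
est_apply.unrolled_estimator <- function(est, params, y_in, mask,
                                         sens = NULL) {
  y <- as_karray(y_in); m <- as_mask_matrix(mask)
  stopifnot(!is.null(sens))
  s <- as_karray(sens)
  unrolled_forward(est, params, y, m, s)$f
}

#' @export
est_value_grad.unrolled_estimator <- function(est, params, y_in, mask,
                                              sens = NULL, target,
                                              weight2 = NULL) {
  y <- as_karray(y_in); m <- as_mask_matrix(mask)
  t0 <- as_karray(target)
  stopifnot(!is.null(sens))
  s <- as_karray(sens)
  h <- dim(y)[1]; wd <- dim(y)[2]; n <- h * wd
  fw <- unrolled_forward(est, params, y, m, s, keep_cache = TRUE)
  r <- fw$f - t0
  w2 <- if (is.null(weight2)) NULL else weight2
  loss <- if (is.null(w2)) sum(Mod(r)^2) else sum(bcast_mult(w2, Mod(r)^2))

  g <- if (is.null(w2)) r else bcast_mult(w2, r)
  gk <- vector("list", est$blocks)
  ge <- numeric(est$blocks)
  for (b in rev(seq_len(est$blocks))) {
    cc <- fw$cache[[b]]
    ge[b] <- -2 * Re(sum(Conj(g) * bcast_mult(m, cc$kp - y)))
    gkp <- bcast_mult(1 - params$eta[b] * m, g)
    gx2 <- coil_combine(gkp, s)
    Ug <- stats::fft(gx2) / sqrt(n)
    gx <- gx2 + stats::fft(Ug * Conj(cc$Wf), inverse = TRUE) / sqrt(n)
    gWf <- Conj(cc$Ux) * Ug
    gk[[b]] <- extract_kernel(stats::fft(gWf, inverse = TRUE), est$kernel_size)
    g <- coil_expand(gx, s)
  }
  list(loss = loss, grads = list(kernels = gk, eta = ge))
}

# --- diagonal affine estimator ----------------------------------------------

#' Diagonal affine k-space estimator
#'
#' The simplest member of the estimator contract: per-location complex gain
#' and offset, `f_j = a_j y_j + b_j`, shared across coils. Rich enough to
#' represent the conditional-expectation map of the discrete toy ensembles
#' (where each coordinate's posterior mean depends only on whether that
#' coordinate was observed), so it is the estimator used to check that
#' gradient training actually converges to the enumerated conditional
#' expectations.
#'
#' @return an estimator object.
#' @export
diagonal_estimator <- function() {
  structure(list(), class = c("diagonal_estimator", "kspace_estimator"))
}

#' @export
est_init.diagonal_estimator <- function(est, h, w) {
  z <- matrix(complex(real = 0, imaginary = 0), h, w)
  list(a = z, b = z)
}

#' @export
est_apply.diagonal_estimator <- function(est, params, y_in, mask,
                                         sens = NULL) {
  y <- as_karray(y_in)
  out <- y
  for (cc in seq_len(dim(y)[3])) {
    out[, , cc] <- params$a * y[, , cc] + params$b
  }
  out
}

#' @export
est_value_grad.diagonal_estimator <- function(est, params, y_in, mask,
                                              sens = NULL, target,
                                              weight2 = NULL) {
  y <- as_karray(y_in); t0 <- as_karray(target)
  f <- est_apply(est, params, y, mask, sens)
  r <- f - t0
  loss <- if (is.null(weight2)) sum(Mod(r)^2) else
    sum(bcast_mult(weight2, Mod(r)^2))
  g <- if (is.null(weight2)) r else bcast_mult(weight2, r)
  ga <- gb <- matrix(complex(real = 0, imaginary = 0), dim(y)[1], dim(y)[2])
  for (cc in seq_len(dim(y)[3])) {
    ga <- ga + g[, , cc] * Conj(y[, , cc])
    gb <- gb + g[, , cc]
  }
  list(loss = loss, grads = list(a = ga, b = gb))
}

# --- parameter flattening (for the optimizer) -------------------------------

flatten_params <- function(p) {
  out <- c()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.complex(x)) {
      out <<- c(out, as.vector(Re(x)), as.vector(Im(x)))
    } else {
      out <<- c(out, as.vector(x))
    }
  }
  walk(p)
  out
}

unflatten_params <- function(vec, template) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      lapply(x, walk)
    } else if (is.complex(x)) {
      n <- length(x)
      re <- vec[pos + seq_len(n)]; pos <<- pos + n
      im <- vec[pos + seq_len(n)]; pos <<- pos + n
      array(complex(real = re, imaginary = im), dim = dim(x) %||% n)
    } else {
      n <- length(x)
      v <- vec[pos + seq_len(n)]; pos <<- pos + n
      array(v, dim = dim(x) %||% n)
    }
  }
  out <- walk(template)
  stopifnot(pos == length(vec))
  out
}

# Real gradient vector matching flatten_params layout: complex analytic
# gradients g contribute (2 Re g, 2 Im g).
flatten_grads <- function(g) {
  out <- c()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.complex(x)) {
      out <<- c(out, 2 * as.vector(Re(x)), 2 * as.vector(Im(x)))
    } else {
      out <<- c(out, as.vector(x))
    }
  }
  walk(g)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
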