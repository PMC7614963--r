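#' Method specifications (loss weighting + partition structure + inference)
#'
#' Each method is a combination of a loss weighting `W`, a structure for
#' the partitioning-mask distribution, and a pair of inference estimators
#' (one for a doubly sub-sampled network input, one for a singly
#' sub-sampled input):
#'
#' | name                 | weighting                          | partition mask |
#' |----------------------|------------------------------------|----------------|
#' | `unweighted_n2n`     | identity                           | 1D column-wise |
#' | `ssdu_2d`            | `(1 - M_Lambda) M_Omega`           | 2D Bernoulli   |
#' | `ssdu_1d`            | `(1 - M_Lambda) M_Omega`           | 1D column-wise |
#' | `kweighted_ssdu_1d`  | `(1-K)^{-1/2}(1 - M_Lambda)M_Omega`| 1D column-wise |
#' | `supervised`         | identity, target is reference data | none           |
#'
#' `unweighted_n2n` requires the `(1 - K)^{-1}` correction at inference;
#' the SSDU variants do not.
#'
#' @param name one of the method names above.
#' @return an object of class `method_spec`.
#' @export
method_spec <- function(name = c("unweighted_n2n", "ssdu_2d", "ssdu_1d",
                                 "kweighted_ssdu_1d", "supervised")) {
  name <- match.arg(name)
  tab <- list(
    unweighted_n2n = list(weighting = "identity", lambda_structure = "column_1d",
                          tilde_estimate = "n2n_dc", singly_estimate = "n2n_plain",
                          self_supervised = TRUE),
    ssdu_2d = list(weighting = "ssdu_mask", lambda_structure = "bernoulli_2d",
                   tilde_estimate = "ssdu_dc", singly_estimate = "ssdu_plain",
                   self_supervised = TRUE),
    ssdu_1d = list(weighting = "ssdu_mask", lambda_structure = "column_1d",
                   tilde_estimate = "ssdu_dc", singly_estimate = "ssdu_plain",
                   self_supervised = TRUE),
    kweighted_ssdu_1d = list(weighting = "k_half_ssdu_mask",
                             lambda_structure = "column_1d",
                             tilde_estimate = "ssdu_dc",
                             singly_estimate = "ssdu_plain",
                             self_supervised = TRUE),
    supervised = list(weighting = "identity", lambda_structure = "none",
                      tilde_estimate = "plain", singly_estimate = "plain",
                      self_supervised = FALSE)
  )
  structure(c(list(name = name), tab[[name]]), class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat(sprintf("method_spec: %s (weighting %s, partition %s, %s)\n",
              x$name, x$weighting, x$lambda_structure,
              if (x$self_supervised) "self-supervised" else "supervised"))
  invisible(x)
}

# Squared per-location loss weight W^2 for a method. For the K-weighted
# SSDU variant the squared weight is (1-k)^{-1} on the loss set.
loss_weight2 <- function(spec, omega = NULL, lam = NULL, K = NULL) {
  switch(spec$weighting,
    identity = NULL,  # interpreted as all-ones
    ssdu_mask = {
      stopifnot(!is.null(omega), !is.null(lam))
      (1 - as_mask_matrix(lam)) * as_mask_matrix(omega)
    },
    k_half_ssdu_mask = {
      if (is.null(K)) {
        stop("K-weighted SSDU requires a correction matrix K", call. = FALSE)
      }
      stopifnot(!is.null(omega), !is.null(lam))
      as_kmat(K)$w1 * (1 - as_mask_matrix(lam)) * as_mask_matrix(omega)
    },
    stop("unknown weighting", call. = FALSE)
  )
}

#' Weighted squared-error training loss
#'
#' Computes `||W (f_out - target)||_2^2` summed over k-space locations and
#' coils, where the diagonal weight `W` is selected by the method
#' specification: the identity, the SSDU loss mask
#' `(1 - M_Lambda) M_Omega`, or its K-weighted version
#' `(1-K)^{-1/2} (1 - M_Lambda) M_Omega`. Complex residuals enter through
#' their squared magnitude; diagonal weights broadcast across coils.
#'
#' @param f_out network output, complex `(H, W, C)` array.
#' @param target regression target (`y` for self-supervised methods, the
#'   reference `y0` for supervised training), same shape.
#' @param omega,lam acquisition and partitioning masks (needed for the
#'   masked weightings).
#' @param K [k_matrix][compute_K], needed for the K-weighted variant.
#' @param spec a [method_spec()].
#' @return single non-negative number.
#' @export
weighted_l2_loss <- function(f_out, target, omega = NULL, lam = NULL,
                             K = NULL, spec = method_spec("supervised")) {
  f <- as_karray(f_out); y <- as_karray(target)
  stopifnot(all(dim(f) == dim(y)))
  w2 <- loss_weight2(spec, omega, lam, K)
  r2 <- Mod(f - y)^2
  if (is.null(w2)) sum(r2) else sum(bcast_mult(w2, r2))
}

#' Decomposition of a weighted loss into SSDU and complement terms
#'
#' For a network output that is exactly consistent with the doubly
#' sub-sampled data (`M_Lambda M_Omega f = M_Lambda M_Omega y`), any
#' diagonally weighted squared loss splits exactly as
#' \deqn{\|W(f - y)\|^2 = \|W(1-M_\Lambda)M_\Omega(f - y)\|^2 +
#'   \|W(1-M_\Omega)f\|^2,}
#' i.e. the SSDU loss plus a contribution from unacquired locations. Under
#' the SSDU weighting the complement term vanishes identically, which is
#' why SSDU needs no correction at inference while an identity-weighted
#' loss does.
#'
#' @param f_out network output consistent with the doubly sub-sampled data.
#' @param y acquired k-space (`M_Omega y0`), same shape.
#' @param omega,lam acquisition and partitioning masks.
#' @param W2 squared diagonal weight (`H x W` non-negative matrix), or
#'   `NULL` for the identity.
#' @param tol relative tolerance for the consistency precondition.
#' @return list with `ssdu_term`, `complement_term` and their sum `total`.
#' @export
loss_decomposition <- function(f_out, y, omega, lam, W2 = NULL, tol = 1e-8) {
  f <- as_karray(f_out); yy <- as_karray(y)
  mo <- as_mask_matrix(omega); ml <- as_mask_matrix(lam)
  mb <- ml * mo
  dev <- sqrt(sum(Mod(bcast_mult(mb, f - yy))^2))
  scale <- sqrt(sum(Mod(yy)^2)) + 1e-300
  if (dev / scale > tol) {
    stop("f_out is not consistent with the doubly sub-sampled data ",
         "(M_Lambda M_Omega f != M_Lambda M_Omega y)", call. = FALSE)
  }
  w2 <- if (is.null(W2)) matrix(1, nrow(mo), ncol(mo)) else W2
  ssdu_term <- sum(bcast_mult(w2 * (1 - ml) * mo, Mod(f - yy)^2))
  complement_term <- sum(bcast_mult(w2 * (1 - mo), Mod(f)^2))
  list(ssdu_term = ssdu_term, complement_term = complement_term,
       total = ssdu_term + complement_term)
}
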