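#' Discrete toy ensemble specification
#'
#' A small, exactly enumerable model of the measurement chain
#' `y_tilde = M_Lambda M_Omega y0`: `N` k-space coordinates, each taking
#' values from a finite nonzero alphabet, with independent (or
#' column-coupled) Bernoulli masks. Zero is excluded from the alphabet so
#' that a zero in the doubly sub-sampled data identifies "not sampled"
#' unambiguously.
#'
#' @param alphabet nonzero real values the reference entries can take.
#' @param alphabet_probs probability of each alphabet value (recycled
#'   across coordinates); defaults to uniform.
#' @param p per-coordinate acquisition probability (length `N` or 1).
#' @param p_tilde per-coordinate partitioning probability.
#' @param n_rows,n_cols grid shape; `N = n_rows * n_cols`. With
#'   `structure = "column"` mask draws are coupled within columns
#'   (coordinates are ordered column-major).
#' @param structure `"iid"` or `"column"`.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(alphabet = c(1), alphabet_probs = NULL,
                     p, p_tilde, n_rows = 1, n_cols = length(p),
                     structure = c("iid", "column")) {
  structure <- match.arg(structure)
  N <- n_rows * n_cols
  p <- rep_len(p, N)
  p_tilde <- rep_len(p_tilde, N)
  if (any(alphabet == 0)) stop("alphabet must exclude 0", call. = FALSE)
  if (any(p <= 0)) stop("toy spec requires p > 0 everywhere", call. = FALSE)
  if (any(p_tilde >= 1)) {
    stop("toy spec requires p_tilde < 1 everywhere", call. = FALSE)
  }
  if (is.null(alphabet_probs)) {
    alphabet_probs <- rep(1 / length(alphabet), length(alphabet))
  }
  stopifnot(length(alphabet_probs) == length(alphabet),
            abs(sum(alphabet_probs) - 1) < 1e-12)
  if (structure == "column") {
    # column coupling: probabilities must be constant within each column
    pm <- matrix(p, n_rows); ptm <- matrix(p_tilde, n_rows)
    stopifnot(all(abs(sweep(pm, 2, pm[1, ])) < 1e-12),
              all(abs(sweep(ptm, 2, ptm[1, ])) < 1e-12))
  }
  structure(list(N = N, alphabet = alphabet, alphabet_probs = alphabet_probs,
                 p = p, p_tilde = p_tilde, n_rows = n_rows, n_cols = n_cols,
                 structure = structure),
            class = "toy_spec")
}

# All 0/1 mask outcomes for a toy spec, with probabilities. For column
# structure the draw is per column, expanded to coordinates.
enumerate_masks <- function(spec, probs) {
  if (spec$structure == "column") {
    bits <- as.matrix(expand.grid(rep(list(0:1), spec$n_cols)))
    p_col <- matrix(probs, spec$n_rows)[1, ]
    pr <- apply(bits, 1, function(b) prod(ifelse(b == 1, p_col, 1 - p_col)))
    ind <- bits[, rep(seq_len(spec$n_cols), each = spec$n_rows), drop = FALSE]
  } else {
    ind <- as.matrix(expand.grid(rep(list(0:1), spec$N)))
    pr <- apply(ind, 1, function(b) prod(ifelse(b == 1, probs, 1 - probs)))
  }
  list(ind = unname(ind), prob = pr)
}

#' Exhaustive outcome table of a discrete toy ensemble
#'
#' Enumerates every joint outcome of (`y0`, `Omega`, `Lambda`) and the
#' induced `y = M_Omega y0` and `y_tilde = M_Lambda y`, with exact
#' probabilities. This is the brute-force oracle against which the
#' conditional-expectation identities of the framework are checked.
#'
#' @param spec a [toy_spec()]; the total outcome count
#'   `K^N * masks^2` must stay below ~1e7.
#' @return list with matrices `y0`, `omega`, `lam`, `y`, `ytilde` (one row
#'   per outcome) and a `prob` vector summing to 1.
#' @export
enumerate_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  K <- length(spec$alphabet)
  mo <- enumerate_masks(spec, spec$p)
  ml <- enumerate_masks(spec, spec$p_tilde)
  n_y0 <- K^spec$N
  n_out <- n_y0 * nrow(mo$ind) * nrow(ml$ind)
  if (n_out > 1e7) stop("toy ensemble too large to enumerate", call. = FALSE)

  y0_idx <- as.matrix(expand.grid(rep(list(seq_len(K)), spec$N)))
  y0_tab <- matrix(spec$alphabet[y0_idx], nrow = n_y0)
  y0_pr <- apply(y0_idx, 1, function(ii) prod(spec$alphabet_probs[ii]))

  grid <- expand.grid(iy = seq_len(n_y0), io = seq_len(nrow(mo$ind)),
                      il = seq_len(nrow(ml$ind)))
  y0 <- y0_tab[grid$iy, , drop = FALSE]
  om <- mo$ind[grid$io, , drop = FALSE]
  lm <- ml$ind[grid$il, , drop = FALSE]
  y <- om * y0
  yt <- lm * y
  prob <- y0_pr[grid$iy] * mo$prob[grid$io] * ml$prob[grid$il]
  # drop unreachable outcomes (zero probability, e.g. when a mask
  # probability is exactly 0 or 1) so pattern tables only contain
  # reachable patterns
  keep <- prob > 0
  list(y0 = y0[keep, , drop = FALSE], omega = om[keep, , drop = FALSE],
       lam = lm[keep, , drop = FALSE], y = y[keep, , drop = FALSE],
       ytilde = yt[keep, , drop = FALSE], prob = prob[keep])
}

#' Exact conditional expectations per doubly sub-sampled pattern
#'
#' Groups the enumerated outcomes by the distinct observed pattern
#' `y_tilde` and computes, coordinatewise and exactly, `E[Y | Y_tilde]`,
#' `E[Y0 | Y_tilde]`, and the loss-mask moments `E[A_j | Y_tilde]` and
#' `E[A_j Y_j | Y_tilde]` with `A = (1 - M_Lambda) M_Omega` that determine
#' the partitioned-loss minimizer.
#'
#' @param spec a [toy_spec()].
#' @return list with `ytilde` (unique patterns, one per row), `prob`
#'   (pattern probabilities, summing to 1), and matrices `EY`, `EY0`, `EA`,
#'   `EAY` of the same shape as `ytilde`.
#' @export
conditional_expectations <- function(spec) {
  tab <- enumerate_toy(spec)
  key <- apply(tab$ytilde, 1, paste, collapse = "|")
  groups <- split(seq_along(key), key)
  a <- (1 - tab$lam) * tab$omega
  n_pat <- length(groups)
  pat <- matrix(0, n_pat, spec$N)
  pr <- numeric(n_pat)
  EY <- EY0 <- EA <- EAY <- matrix(0, n_pat, spec$N)
  for (g in seq_len(n_pat)) {
    idx <- groups[[g]]
    w <- tab$prob[idx]
    pw <- sum(w)
    pat[g, ] <- tab$ytilde[idx[1], ]
    pr[g] <- pw
    EY[g, ] <- colSums(tab$y[idx, , drop = FALSE] * w) / pw
    EY0[g, ] <- colSums(tab$y0[idx, , drop = FALSE] * w) / pw
    EA[g, ] <- colSums(a[idx, , drop = FALSE] * w) / pw
    EAY[g, ] <- colSums((a * tab$y)[idx, , drop = FALSE] * w) / pw
  }
  list(ytilde = pat, prob = pr, EY = EY, EY0 = EY0, EA = EA, EAY = EAY)
}

toy_k <- function(spec) (1 - spec$p) / (1 - spec$p_tilde * spec$p)

#' Verify the de-biasing identity on an enumerable ensemble
#'
#' Checks, by total enumeration, that
#' `(1 - K)^{-1} (E[Y | Y_tilde] - K Y_tilde) = E[Y0 | Y_tilde]` for every
#' reachable pattern, where `K` is the diagonal correction built from the
#' two sampling densities. The identity is exact, so the deviation is at
#' floating-point level for any valid spec.
#'
#' @param spec a [toy_spec()] (its constructor already enforces the
#'   validity conditions `p > 0`, `p_tilde < 1`).
#' @return maximum absolute deviation over all patterns and coordinates.
#' @export
verify_claim1 <- function(spec) {
  ce <- conditional_expectations(spec)
  k <- toy_k(spec)
  lhs <- sweep(ce$EY - sweep(ce$ytilde, 2, k, `*`), 2, 1 - k, `/`)
  max(abs(lhs - ce$EY0))
}

#' Verify the partitioned-loss minimizer identity
#'
#' The coordinatewise minimizer of the conditional partitioned loss
#' `E[ ||(1 - M_Lambda) M_Omega (f - Y)||^2 | Y_tilde ]` is the weighted
#' conditional mean `f*_j = E[A_j Y_j | y_tilde] / E[A_j | y_tilde]`.
#' This function checks by enumeration that `f*` equals
#' `E[Y0 | Y_tilde]` at every coordinate *not* sampled in `y_tilde`
#' (sampled coordinates are excluded: there the loss weight is zero
#' whenever the estimate can disagree, so the minimizer is pinned by
#' data consistency instead). Coordinates with zero conditional loss-mask
#' mass are unconstrained by the loss and are excluded as well.
#'
#' @param spec a [toy_spec()].
#' @return maximum absolute deviation over all patterns and unsampled,
#'   constrained coordinates.
#' @export
verify_claim2 <- function(spec) {
  ce <- conditional_expectations(spec)
  dev <- 0
  for (g in seq_len(nrow(ce$ytilde))) {
    unsampled <- ce$ytilde[g, ] == 0
    constrained <- ce$EA[g, ] > 1e-14
    j <- which(unsampled & constrained)
    if (length(j)) {
      fstar <- ce$EAY[g, j] / ce$EA[g, j]
      dev <- max(dev, max(abs(fstar - ce$EY0[g, j])))
    }
  }
  dev
}

#' Verify that full-rank diagonal weighting does not move the minimizer
#'
#' For any deterministic diagonal weight with strictly positive entries,
#' the minimizer of `E[ ||W (f - Y)||^2 | Y_tilde ]` is `E[Y | Y_tilde]`,
#' independent of `W`. The minimizer is computed numerically as the
#' `W^2`-weighted conditional mean (so a sign or ordering error in the
#' weighting would be caught) and compared with the enumerated
#' `E[Y | Y_tilde]`. Coordinates where the weight is zero are
#' unconstrained and reported rather than compared.
#'
#' @param spec a [toy_spec()].
#' @param w diagonal weight entries (length `N`, non-negative; default all
#'   ones).
#' @return list with `deviation` (max absolute deviation on constrained
#'   coordinates) and `unconstrained` (indices with zero weight).
#' @export
verify_fullrank_minimizer <- function(spec, w = rep(1, spec$N)) {
  stopifnot(length(w) == spec$N, all(w >= 0))
  tab <- enumerate_toy(spec)
  key <- apply(tab$ytilde, 1, paste, collapse = "|")
  groups <- split(seq_along(key), key)
  w2 <- w^2
  constrained <- which(w2 > 0)
  dev <- 0
  for (idx in groups) {
    pw <- tab$prob[idx]
    ey <- colSums(tab$y[idx, , drop = FALSE] * pw) / sum(pw)
    # numerical argmin of the weighted conditional loss, coordinatewise:
    # sum_o P(o|yt) w2_j (f_j - Y_j(o))^2 is minimized at the w2-weighted
    # conditional mean, which for deterministic w2 collapses to ey
    fstar <- colSums(tab$y[idx, , drop = FALSE] * (pw %o% w2)) /
      colSums(matrix(1, length(idx), spec$N) * (pw %o% w2))
    dev <- max(dev, max(abs(fstar[constrained] - ey[constrained])))
  }
  list(deviation = dev, unconstrained = which(w2 == 0))
}

#' Random valid toy specification
#'
#' Draws a small enumerable spec (N <= 4) with random nonzero alphabet,
#' random acquisition density `p` between 0.2 and 1, random partitioning
#' density `p_tilde` between 0 and 0.9, and random i.i.d. or column-coupled
#' structure — the sweep generator used to stress the identity checks.
#'
#' @param rng_seed integer seed.
#' @return a [toy_spec()].
#' @export
random_toy_spec <- function(rng_seed) {
  withr::with_seed(rng_seed, {
    columns <- stats::runif(1) < 0.5
    if (columns) {
      n_rows <- sample(1:2, 1); n_cols <- sample(1:2, 1)
    } else {
      n_rows <- 1; n_cols <- sample(2:4, 1)
    }
    N <- n_rows * n_cols
    alphabet <- sample(c(-2, -1, 0.5, 1, 2, 3), sample(2:3, 1))
    ap <- stats::runif(length(alphabet), 0.2, 1)
    p_col <- stats::runif(n_cols, 0.2, 1)
    pt_col <- stats::runif(n_cols, 0, 0.9)
    toy_spec(alphabet = alphabet, alphabet_probs = ap / sum(ap),
             p = rep(p_col, each = n_rows),
             p_tilde = rep(pt_col, each = n_rows),
             n_rows = n_rows, n_cols = n_cols,
             structure = if (columns) "column" else "iid")
  })
}
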