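#' Self-supervised / supervised training loop
#'
#' Trains an estimator with the Adam optimizer at a fixed learning rate,
#' one gradient step per slice per epoch (batch size 1). For
#' self-supervised methods the partitioning mask is re-drawn for every
#' slice once per epoch from `lambda_dist` (seeded per `(epoch, slice)`,
#' so runs are exactly reproducible), the network input is the doubly
#' sub-sampled data `y_tilde = M_Lambda y`, and the regression target is
#' the acquired data `y` under the method's loss weighting. Supervised
#' training uses the acquired data as input and the fully sampled
#' reference as target, and errors when the dataset's reference access is
#' locked.
#'
#' @param method a [method_spec()] or method name.
#' @param dataset an [ss_dataset][make_dataset].
#' @param estimator an estimator object (see [compact_unrolled_estimator()]).
#' @param epochs number of epochs (default 50).
#' @param lr fixed Adam learning rate (default 1e-3).
#' @param rng_seed master seed for all partitioning-mask draws.
#' @param lambda_dist partitioning-mask distribution; required for
#'   self-supervised methods, must satisfy `p_tilde < 1` everywhere.
#' @param K [k_matrix][compute_K]; required for the K-weighted loss and
#'   for Noisier2Noise inference. Computed from `dataset$omega_dist` and
#'   `lambda_dist` when omitted and needed.
#' @param init_params optional warm-start parameters (e.g. from a previous
#'   fit); defaults to the estimator's initialization.
#' @param verbose print per-epoch losses.
#' @return an object of class `ss_fit` with elements `params`, `history`
#'   (data.frame of per-epoch mean training loss), `method`, `estimator`,
#'   `lambda_dist`, `K`.
#' @export
train <- function(method, dataset, estimator, epochs = 50, lr = 1e-3,
                  rng_seed = 1, lambda_dist = NULL, K = NULL,
                  init_params = NULL, verbose = FALSE) {
  spec <- if (inherits(method, "method_spec")) method else method_spec(method)
  stopifnot(inherits(dataset, "ss_dataset"))
  h <- dataset$grid[1]; w <- dataset$grid[2]

  if (spec$self_supervised) {
    if (is.null(lambda_dist)) {
      stop("self-supervised training requires a partitioning-mask ",
           "distribution (lambda_dist)", call. = FALSE)
    }
    if (any(lambda_dist$prob >= 1)) {
      stop("partitioning density must satisfy p_tilde < 1 everywhere; ",
           "build it with a cap_epsilon", call. = FALSE)
    }
    if (spec$weighting == "k_half_ssdu_mask" && is.null(K)) {
      K <- compute_K(dataset$omega_dist, lambda_dist)
    }
  } else if (!isTRUE(dataset$reference_access)) {
    stop("supervised training requested but the dataset's reference ",
         "k-space access is disabled", call. = FALSE)
  }
  if (is.null(K) && spec$name == "unweighted_n2n" && !is.null(lambda_dist)) {
    K <- compute_K(dataset$omega_dist, lambda_dist)
  }

  params <- if (is.null(init_params)) est_init(estimator, h, w) else init_params
  theta <- flatten_params(params)
  opt <- adam_state(length(theta), lr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0))

  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in seq_along(dataset$records)) {
      rec <- dataset$records[[i]]
      if (spec$self_supervised) {
        lam <- sample_mask(lambda_dist,
                           rng_seed = derive_seed(rng_seed, ep, rec$slice_id))
        m_in <- lam$mask * rec$omega$mask
        y_in <- bcast_mult(m_in, rec$y$data)
        target <- rec$y$data
        w2 <- loss_weight2(spec, rec$omega, lam, K)
      } else {
        m_in <- rec$omega$mask
        y_in <- rec$y$data
        target <- get_reference(dataset, i)$data
        w2 <- NULL
      }
      params <- unflatten_params(theta, params)
      vg <- est_value_grad(estimator, params, y_in, m_in, rec$sens,
                           target = target, weight2 = w2)
      theta <- adam_step(opt, theta, flatten_grads(vg$grads))
      tot <- tot + vg$loss
    }
    history <- rbind(history,
                     data.frame(epoch = ep,
                                train_loss = tot / length(dataset$records)))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.6g", ep, tot / length(dataset$records)))
    }
  }
  structure(list(params = unflatten_params(theta, params), history = history,
                 method = spec, estimator = estimator,
                 lambda_dist = lambda_dist, K = K, lr = lr, seed = rng_seed),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("ss_fit: %s, %d epochs, final training loss %s\n",
              x$method$name, nrow(x$history),
              if (nrow(x$history)) sprintf("%.6g", x$history$train_loss[nrow(x$history)])
              else "(untrained)"))
  invisible(x)
}

# Adam with bias correction; state lives in an environment.
adam_state <- function(n, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- numeric(n); e$v <- numeric(n); e$t <- 0L
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(st, theta, grad) {
  st$t <- st$t + 1L
  st$m <- st$beta1 * st$m + (1 - st$beta1) * grad
  st$v <- st$beta2 * st$v + (1 - st$beta2) * grad^2
  mhat <- st$m / (1 - st$beta1^st$t)
  vhat <- st$v / (1 - st$beta2^st$t)
  theta - st$lr * mhat / (sqrt(vhat) + st$eps)
}

#' Reconstruct k-space with a trained estimator
#'
#' Routes the network output through the inference estimator the method
#' prescribes. With `input_mode = "tilde"` the network sees doubly
#' sub-sampled data (a partitioning mask is drawn unless supplied) and the
#' data-consistent estimate is returned; with `input_mode = "singly"` the
#' network sees all acquired data and the plain estimate is returned
#' (with the `(1 - K)^{-1}` de-biasing for unweighted Noisier2Noise).
#'
#' @param fit an `ss_fit` from [train()].
#' @param y acquired k-space (`kspace_data` or complex array).
#' @param omega acquisition mask of `y`.
#' @param sens coil sensitivities.
#' @param input_mode `"tilde"` or `"singly"`.
#' @param lam optional partitioning mask for `"tilde"` mode; drawn from
#'   the fit's `lambda_dist` when omitted.
#' @param rng_seed seed for that draw.
#' @return complex `(H, W, C)` k-space estimate.
#' @export
reconstruct <- function(fit, y, omega, sens,
                        input_mode = c("singly", "tilde"),
                        lam = NULL, rng_seed = NULL) {
  stopifnot(inherits(fit, "ss_fit"))
  input_mode <- match.arg(input_mode)
  spec <- fit$method
  yy <- as_karray(y)
  mo <- as_mask_matrix(omega)

  if (input_mode == "tilde" && spec$self_supervised) {
    if (is.null(lam)) {
      if (is.null(fit$lambda_dist)) {
        stop("tilde input mode needs a partitioning mask or distribution",
             call. = FALSE)
      }
      lam <- sample_mask(fit$lambda_dist, rng_seed = rng_seed)
    }
    ml <- as_mask_matrix(lam)
    m_in <- ml * mo
    f <- est_apply(fit$estimator, fit$params, bcast_mult(m_in, yy), m_in, sens)
    route <- spec$tilde_estimate
  } else {
    f <- est_apply(fit$estimator, fit$params, yy, mo, sens)
    route <- spec$singly_estimate
  }

  switch(route,
    n2n_dc = {
      if (is.null(fit$K)) stop("Noisier2Noise inference requires K", call. = FALSE)
      n2n_correct_dc(f, yy, mo, fit$K)
    },
    n2n_plain = {
      if (is.null(fit$K)) stop("Noisier2Noise inference requires K", call. = FALSE)
      n2n_correct_plain(f, yy, fit$K)
    },
    ssdu_dc = ssdu_estimate(f, yy, mo, "dc_tilde_input"),
    ssdu_plain = ssdu_estimate(f, yy, mo, "plain_y_input"),
    plain = f
  )
}

#' Mean test-set k-space NMSE of a fit
#'
#' Convenience evaluation helper: reconstructs every record of a dataset
#' and averages the k-space NMSE against the fully sampled reference.
#'
#' @param fit an `ss_fit`.
#' @param dataset an `ss_dataset` with reference access enabled.
#' @param input_mode passed to [reconstruct()].
#' @param rng_seed base seed for any partitioning-mask draws.
#' @return mean NMSE over records.
#' @export
evaluate_fit <- function(fit, dataset, input_mode = "singly", rng_seed = 1) {
  vals <- vapply(seq_along(dataset$records), function(i) {
    rec <- dataset$records[[i]]
    est <- reconstruct(fit, rec$y, rec$omega, rec$sens,
                       input_mode = input_mode,
                       rng_seed = derive_seed(rng_seed, 4L, i))
    nmse(est, get_reference(dataset, i))
  }, numeric(1))
  mean(vals)
}
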