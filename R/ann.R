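#' Multilayer-perceptron configuration
#'
#' One hidden layer of tangent-sigmoid units and a linear output layer,
#' trained in full batch by Levenberg-Marquardt. Defaults: 7 hidden neurons
#' and 4 output neurons.
#'
#' @param n_inputs Number of input features.
#' @param n_hidden Hidden-layer size (default 7).
#' @param n_outputs Output-layer size (default 4).
#' @param lambda0 Initial LM damping (default 1e-2).
#' @param lambda_factor Damping multiplier/divisor on rejected/accepted
#'   steps (default 10).
#' @param max_iter Maximum LM iterations (default 100).
#' @param tol Relative loss-improvement tolerance (default 1e-9).
#' @param max_lambda Damping bound; exceeding it stops training (default
#'   1e10).
#' @param seed Weight-initialisation seed.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(n_inputs, n_hidden = 7L, n_outputs = 4L,
                       lambda0 = 1e-2, lambda_factor = 10,
                       max_iter = 100L, tol = 1e-9, max_lambda = 1e10,
                       seed = 1L) {
  if (n_inputs < 1L || n_hidden < 1L || n_outputs < 1L)
    stop("mlp_config: all layer sizes must be >= 1")
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs),
                 lambda0 = lambda0, lambda_factor = lambda_factor,
                 max_iter = as.integer(max_iter), tol = tol,
                 max_lambda = max_lambda, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Initialise MLP weights
#'
#' Seeded uniform initialisation scaled by 1/sqrt(fan-in).
#'
#' @param config An [mlp_config()].
#' @param scale Multiplier on the init range (0 gives all-zero weights).
#' @return An `mlp_weights` object: `W1` (hidden x inputs), `b1`, `W2`
#'   (outputs x hidden), `b2`, plus the `config`.
#' @export
mlp_init <- function(config, scale = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  r1 <- scale / sqrt(config$n_inputs)
  r2 <- scale / sqrt(config$n_hidden)
  structure(list(
    W1 = matrix(stats::runif(config$n_hidden * config$n_inputs, -r1, r1),
                config$n_hidden, config$n_inputs),
    b1 = stats::runif(config$n_hidden, -r1, r1),
    W2 = matrix(stats::runif(config$n_outputs * config$n_hidden, -r2, r2),
                config$n_outputs, config$n_hidden),
    b2 = stats::runif(config$n_outputs, -r2, r2),
    config = config), class = "mlp_weights")
}

#' Flatten MLP weights to a vector
#' @param weights An `mlp_weights`.
#' @return Numeric vector (W1, b1, W2, b2 in order).
#' @export
mlp_flatten <- function(weights)
  c(as.numeric(weights$W1), weights$b1, as.numeric(weights$W2), weights$b2)

#' Rebuild MLP weights from a flat vector
#' @param weights Template `mlp_weights` (defines shapes).
#' @param v Numeric vector from [mlp_flatten()].
#' @return An `mlp_weights`.
#' @export
mlp_unflatten <- function(weights, v) {
  cfg <- weights$config
  n1 <- cfg$n_hidden * cfg$n_inputs
  n2 <- cfg$n_hidden
  n3 <- cfg$n_outputs * cfg$n_hidden
  n4 <- cfg$n_outputs
  if (length(v) != n1 + n2 + n3 + n4)
    stop("mlp_unflatten: wrong vector length")
  weights$W1 <- matrix(v[seq_len(n1)], cfg$n_hidden, cfg$n_inputs)
  weights$b1 <- v[n1 + seq_len(n2)]
  weights$W2 <- matrix(v[n1 + n2 + seq_len(n3)], cfg$n_outputs, cfg$n_hidden)
  weights$b2 <- v[n1 + n2 + n3 + seq_len(n4)]
  weights
}

#' MLP forward pass
#'
#' Y = W2 tanh(W1 x + b1) + b2 per row of X (linear output layer).
#'
#' @param weights An `mlp_weights`.
#' @param X Feature matrix (rows = samples, columns = `n_inputs`).
#' @return Output matrix (rows = samples, columns = `n_outputs`).
#' @export
mlp_forward <- function(weights, X) {
  X <- as.matrix(X)
  if (ncol(X) != weights$config$n_inputs)
    stop("mlp_forward: X has ", ncol(X), " columns, expected ",
         weights$config$n_inputs)
  H <- tanh(sweep(X %*% t(weights$W1), 2, weights$b1, `+`))
  sweep(H %*% t(weights$W2), 2, weights$b2, `+`)
}

# Residual Jacobian d vec(Yhat - Y) / d weights, residuals stacked
# sample-major within each output. Analytic; the network is small enough to
# form it densely.
mlp_jacobian <- function(weights, X) {
  cfg <- weights$config
  n <- nrow(X)
  A <- sweep(X %*% t(weights$W1), 2, weights$b1, `+`)
  H <- tanh(A)
  dH <- 1 - H^2                      # n x n_hidden
  p <- cfg$n_hidden * cfg$n_inputs + cfg$n_hidden +
    cfg$n_outputs * cfg$n_hidden + cfg$n_outputs
  J <- matrix(0, n * cfg$n_outputs, p)
  off_W1 <- 0L
  off_b1 <- cfg$n_hidden * cfg$n_inputs
  off_W2 <- off_b1 + cfg$n_hidden
  off_b2 <- off_W2 + cfg$n_outputs * cfg$n_hidden
  for (o in seq_len(cfg$n_outputs)) {
    rows <- (o - 1L) * n + seq_len(n)
    # W2[o, h] and b2[o]
    for (h in seq_len(cfg$n_hidden))
      J[rows, off_W2 + (h - 1L) * cfg$n_outputs + o] <- H[, h]
    J[rows, off_b2 + o] <- 1
    # W1[h, i] and b1[h] through hidden unit h
    G <- dH * matrix(weights$W2[o, ], n, cfg$n_hidden, byrow = TRUE)
    for (h in seq_len(cfg$n_hidden)) {
      J[rows, off_W1 + (seq_len(cfg$n_inputs) - 1L) * cfg$n_hidden + h] <-
        G[, h] * X
      J[rows, off_b1 + h] <- G[, h]
    }
  }
  J
}

#' Train an MLP by batch Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the full-batch residual Jacobian:
#' (J'J + lambda I) delta = -J'r. Steps that do not decrease the loss are
#' rejected and the damping is multiplied by `lambda_factor`; accepted steps
#' divide it. The recorded loss history is therefore non-increasing.
#'
#' @param weights An `mlp_weights` (e.g. from [mlp_init()]).
#' @param X Feature matrix.
#' @param Y Target matrix (columns = `n_outputs`).
#' @param config Optional [mlp_config()] overriding `weights$config` for
#'   the LM parameters.
#' @return List: `weights` (trained), `history` (data frame of iteration,
#'   loss, lambda, accepted), `converged`.
#' @export
mlp_train_lm <- function(weights, X, Y, config = NULL) {
  cfg <- if (is.null(config)) weights$config else config
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2L) stop("mlp_train_lm: need at least 2 samples")
  if (nrow(Y) != nrow(X) || ncol(Y) != weights$config$n_outputs)
    stop("mlp_train_lm: Y must be n x n_outputs")
  loss_of <- function(w) mean((mlp_forward(w, X) - Y)^2)
  lambda <- cfg$lambda0
  loss <- loss_of(weights)
  hist <- list(data.frame(iteration = 0L, loss = loss, lambda = lambda,
                          accepted = TRUE))
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    r <- as.numeric(mlp_forward(weights, X) - Y)   # sample-major per output
    J <- mlp_jacobian(weights, X)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    v <- mlp_flatten(weights)
    repeat {
      delta <- tryCatch(
        solve(JtJ + diag(lambda, ncol(JtJ)), -g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- mlp_unflatten(weights, v + as.numeric(delta))
        cand_loss <- loss_of(cand)
        if (is.finite(cand_loss) && cand_loss < loss) {
          weights <- cand
          improve <- (loss - cand_loss) / max(loss, .Machine$double.eps)
          loss <- cand_loss
          lambda <- max(lambda / cfg$lambda_factor, 1e-12)
          hist[[length(hist) + 1L]] <-
            data.frame(iteration = it, loss = loss, lambda = lambda,
                       accepted = TRUE)
          if (improve < cfg$tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * cfg$lambda_factor
      if (lambda > cfg$max_lambda) break
    }
    if (converged || lambda > cfg$max_lambda) break
  }
  list(weights = weights, history = do.call(rbind, hist),
       converged = converged)
}

#' Build the lagged-envelope feature matrix for the ANN
#'
#' Each EMG envelope contributes its current sample plus `n_lags` delayed
#' copies; rows before the deepest lag are dropped (returned as attribute
#' `offset`).
#'
#' @param envelopes List of preprocessed envelope `signal_trace`s.
#' @param n_lags Number of lagged samples per channel (default 2).
#' @return Feature matrix with attribute `offset` (number of leading samples
#'   dropped).
#' @export
ann_features <- function(envelopes, n_lags = 2L) {
  if (inherits(envelopes, "signal_trace")) envelopes <- list(envelopes)
  n <- length(envelopes[[1]]$samples)
  rows <- (n_lags + 1L):n
  cols <- list()
  for (e in envelopes)
    for (l in 0:n_lags)
      cols[[length(cols) + 1L]] <- e$samples[rows - l]
  X <- do.call(cbind, cols)
  attr(X, "offset") <- n_lags
  X
}

#' Estimate forces with a trained ANN
#'
#' @param trained `mlp_weights` (as returned in `mlp_train_lm()$weights`).
#' @param envelopes List of preprocessed EMG envelope traces.
#' @param n_force Number of force channels to report (unused network outputs
#'   are dropped).
#' @param n_lags Lags used at training time.
#' @return List of `n_force` `signal_trace`s (first `offset` samples
#'   dropped, stored in attribute `offset`).
#' @export
ann_estimate <- function(trained, envelopes, n_force = 1L, n_lags = 2L) {
  if (inherits(envelopes, "signal_trace")) envelopes <- list(envelopes)
  X <- ann_features(envelopes, n_lags = n_lags)
  Y <- mlp_forward(trained, X)
  fs <- envelopes[[1]]$fs
  out <- lapply(seq_len(n_force), function(j) {
    tr <- signal_trace(Y[, j], fs = fs, label = paste0("F_ann", j),
                       kind = "normalised")
    attr(tr, "offset") <- attr(X, "offset")
    tr
  })
  out
}
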