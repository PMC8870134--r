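#' Linear dynamic block of a Hammerstein-Wiener model
#'
#' Discrete-time transfer function B(q)/F(q) with input delay `nk`:
#' y(k) = b1 w(k-nk) + ... + b_nb w(k-nk-nb+1) - f1 y(k-1) - ... - f_nf y(k-nf)
#' where `f` holds the free coefficients of the monic denominator.
#'
#' @param b Numerator coefficients (length nb >= 1).
#' @param f Free denominator coefficients (length nf >= 0; monic leading 1
#'   implied).
#' @param nk Input delay in samples (>= 0).
#' @return A `linear_block` object.
#' @export
linear_block <- function(b, f = numeric(0), nk = 0L) {
  b <- as.numeric(b); f <- as.numeric(f); nk <- as.integer(nk)
  if (length(b) < 1L) stop("linear_block: need nb >= 1")
  if (nk < 0L) stop("linear_block: nk must be >= 0")
  structure(list(b = b, f = f, nk = nk), class = "linear_block")
}

#' Check stability of a linear block
#'
#' @param block A `linear_block`.
#' @return `TRUE` when every pole of the denominator lies strictly inside the
#'   unit circle.
#' @export
block_is_stable <- function(block) {
  if (length(block$f) == 0L) return(TRUE)
  all(Mod(polyroot(rev(c(1, block$f)))) < 1)
}

# Zero-initial-condition simulation of the linear block; C-level speed via
# stats::filter for both the moving-average and recursive parts.
linear_sim <- function(block, w) {
  n <- length(w)
  wd <- if (block$nk > 0L) c(numeric(block$nk), w)[seq_len(n)] else w
  u <- if (length(block$b) > 1L) {
    v <- stats::filter(c(numeric(length(block$b) - 1L), wd), block$b,
                       method = "convolution", sides = 1)
    as.numeric(v)[length(block$b):(length(block$b) + n - 1L)]
  } else {
    block$b[1] * wd
  }
  if (length(block$f) == 0L) return(u)
  as.numeric(stats::filter(u, -block$f, method = "recursive"))
}

#' Hammerstein-Wiener model
#'
#' Serial association of a static input nonlinearity, a linear dynamic block
#' and a static output nonlinearity.
#'
#' @param input_nl A [static_nl()] (input block).
#' @param linear A [linear_block()].
#' @param output_nl A [static_nl()] (output block).
#' @param converged Logical flag recorded by the identifier (optional).
#' @return A `hw_model` object.
#' @export
hw_model <- function(input_nl, linear, output_nl = static_nl("identity"),
                     converged = NA) {
  stopifnot(inherits(input_nl, "static_nl"), inherits(linear, "linear_block"),
            inherits(output_nl, "static_nl"))
  structure(list(input_nl = input_nl, linear = linear, output_nl = output_nl,
                 converged = converged),
            class = "hw_model")
}

#' @export
print.hw_model <- function(x, ...) {
  cat(sprintf(
    "<hw_model: %s -> B(%d)/F(%d) nk=%d -> %s%s>\n",
    x$input_nl$family, length(x$linear$b), length(x$linear$f), x$linear$nk,
    x$output_nl$family,
    if (isTRUE(x$converged)) ", converged"
    else if (identical(x$converged, FALSE)) ", NOT converged" else ""))
  invisible(x)
}

#' Flat parameter vector of a Hammerstein-Wiener model
#'
#' Packs `[input nl params, b, f, output nl params]`; [hw_unpack_theta()] is
#' the exact inverse.
#'
#' @param model A `hw_model`.
#' @return Numeric vector theta.
#' @export
hw_pack_theta <- function(model) {
  c(nl_get_par(model$input_nl), model$linear$b, model$linear$f,
    nl_get_par(model$output_nl))
}

#' Rebuild a model from a flat parameter vector
#'
#' @param model Template `hw_model` defining the structure and orders.
#' @param theta Numeric vector as produced by [hw_pack_theta()].
#' @return A `hw_model` with the parameters of `theta`.
#' @export
hw_unpack_theta <- function(model, theta) {
  n_in <- nl_npar(model$input_nl)
  nb <- length(model$linear$b); nf <- length(model$linear$f)
  n_out <- nl_npar(model$output_nl)
  if (length(theta) != n_in + nb + nf + n_out)
    stop("hw_unpack_theta: theta length ", length(theta),
         " does not match model parameter count ", n_in + nb + nf + n_out)
  i <- 0L
  model$input_nl <- nl_set_par(model$input_nl, theta[seq_len(n_in)])
  i <- n_in
  model$linear$b <- theta[i + seq_len(nb)]; i <- i + nb
  model$linear$f <- theta[i + seq_len(nf)]; i <- i + nf
  model$output_nl <- nl_set_par(model$output_nl, theta[i + seq_len(n_out)])
  model
}

#' Simulate a Hammerstein-Wiener model
#'
#' y(k) = h(linear_filter(f(u(k)))) with zero initial conditions; the output
#' has the same length and sampling rate as the input. An unstable
#' denominator triggers a warning and flags the result.
#'
#' @param model A `hw_model`.
#' @param u Input `signal_trace` (or bare numeric vector).
#' @return A `signal_trace` of the simulated output (attribute `unstable`
#'   set when the linear block has poles on or outside the unit circle).
#' @export
simulate_hw <- function(model, u) {
  stopifnot(inherits(model, "hw_model"))
  x <- if (inherits(u, "signal_trace")) u$samples else as.numeric(u)
  if (!all(is.finite(x))) stop("simulate_hw: input contains non-finite values")
  unstable <- !block_is_stable(model$linear)
  if (unstable)
    warning("simulate_hw: linear block is unstable; output may diverge")
  w <- eval_nl(model$input_nl, x)
  ylin <- linear_sim(model$linear, w)
  y <- eval_nl(model$output_nl, ylin)
  if (any(!is.finite(y))) stop("simulate_hw: simulation produced non-finite values")
  out <- if (inherits(u, "signal_trace")) {
    signal_trace(y, fs = u$fs, label = paste0(u$label, "_sim"),
                 kind = "normalised")
  } else {
    signal_trace(y, fs = 1, label = "sim", kind = "normalised")
  }
  attr(out, "unstable") <- unstable
  out
}

#' Number of warm-up samples of a model
#'
#' Initial samples affected by the zero initial conditions of the linear
#' block; excluded from error metrics.
#'
#' @param model A `hw_model`.
#' @return Integer warm-up length.
#' @export
hw_warmup <- function(model) {
  max(length(model$linear$b) + model$linear$nk, length(model$linear$f))
}

#' Regression vector at time k
#'
#' phi(k) = \[u_t(k-nk), ..., u_t(k-nk-nb+1), -y(k-1), ..., -y(k-nf)\] with
#' 1-based sample indexing; the linear stage model is y(k) = theta' phi(k)
#' with theta = (b, f).
#'
#' @param u_t Transformed input (numeric vector or `signal_trace`).
#' @param y Output (numeric vector or `signal_trace`).
#' @param k Time index (1-based), at or past the warm-up
#'   `max(nb + nk, nf + 1)`.
#' @param orders List with `nb`, `nf`, `nk`.
#' @return Numeric vector of length nb + nf.
#' @export
build_regressor <- function(u_t, y, k, orders) {
  if (inherits(u_t, "signal_trace")) u_t <- u_t$samples
  if (inherits(y, "signal_trace")) y <- y$samples
  nb <- orders$nb; nf <- orders$nf; nk <- orders$nk
  kmin <- max(nb + nk, nf + 1L)
  if (k < kmin)
    stop("build_regressor: k = ", k, " is below the warm-up index ", kmin)
  u_part <- u_t[k - nk - seq_len(nb) + 1L]
  y_part <- if (nf > 0L) -y[k - seq_len(nf)] else numeric(0)
  c(u_part, y_part)
}

#' Prediction error of a model on given data
#'
#' eps(k) = y(k) - yhat(k), with the first warm-up samples dropped.
#'
#' @param model A `hw_model`.
#' @param u Input `signal_trace`.
#' @param y Measured output `signal_trace`.
#' @return A `signal_trace` of residuals (length = length(y) - warmup).
#' @export
prediction_error <- function(model, u, y) {
  yhat <- simulate_hw(model, u)
  yv <- if (inherits(y, "signal_trace")) y$samples else as.numeric(y)
  if (length(yv) != length(yhat$samples))
    stop("prediction_error: u and y lengths differ")
  w <- hw_warmup(model)
  eps <- (yv - yhat$samples)[(w + 1L):length(yv)]
  signal_trace(eps, fs = yhat$fs, label = "eps", kind = "normalised")
}
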