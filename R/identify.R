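#' Hammerstein-Wiener identification configuration
#'
#' Defaults follow common block-oriented identification practice: a
#' piecewise-linear input nonlinearity with 10 uniformly spaced breakpoints
#' over the observed input range, a second-order linear block with one sample
#' of input delay (nb = 2, nf = 2, nk = 1), an identity output block, and
#' five outer alternating iterations.
#'
#' @param nb,nf,nk Linear block orders (numerator length, free denominator
#'   length, input delay).
#' @param input_family,output_family Nonlinearity family for the input and
#'   output blocks: `"piecewise_linear"`, `"polynomial"` or `"identity"`.
#' @param n_breakpoints Number of piecewise-linear nodes (default 10).
#' @param degree Polynomial degree when a polynomial family is chosen.
#' @param max_iter Maximum outer alternating iterations (default 5).
#' @param tol Relative parameter-change tolerance terminating the outer loop.
#' @param p0_scale RLS initial adaptation scale.
#' @param conv_tol Relative settling tolerance for the RLS convergence flag
#'   (estimate drift over the last 10% of samples).
#' @param enforce_stability Project unstable estimated poles back inside the
#'   unit circle (reflection 1/conj(r)); the identified model is used in
#'   free-run simulation, where an unstable pole — typical when the training
#'   signal excites the dynamics weakly — makes the output diverge.
#' @param sim_regressor After the first outer iteration, build the
#'   regressor's output lags from the model's own simulated linear-stage
#'   output (output-error / pseudolinear regression) instead of the measured
#'   output. Equation-error regression on slowly varying, oversampled
#'   signals collapses onto the trivial one-step predictor (poles near 1,
#'   near-cancelling numerator), which predicts well but simulates poorly;
#'   the simulated-regressor iterations target the free-run simulation the
#'   model is actually used for.
#' @return A `hw_config` list.
#' @export
hw_config <- function(nb = 2L, nf = 2L, nk = 1L,
                      input_family = "piecewise_linear",
                      output_family = "identity",
                      n_breakpoints = 10L, degree = 3L,
                      max_iter = 5L, tol = 1e-6,
                      p0_scale = 1e4, conv_tol = 0.05,
                      enforce_stability = TRUE,
                      sim_regressor = TRUE) {
  structure(list(nb = as.integer(nb), nf = as.integer(nf), nk = as.integer(nk),
                 input_family = input_family, output_family = output_family,
                 n_breakpoints = as.integer(n_breakpoints),
                 degree = as.integer(degree),
                 max_iter = as.integer(max_iter), tol = tol,
                 p0_scale = p0_scale, conv_tol = conv_tol,
                 enforce_stability = isTRUE(enforce_stability),
                 sim_regressor = isTRUE(sim_regressor)),
            class = "hw_config")
}

# Reflect poles with |r| >= 1 to 1/conj(r) (slightly damped), keeping the
# denominator monic and real.
stabilise_f <- function(f, margin = 0.999) {
  if (length(f) == 0L) return(f)
  r <- polyroot(rev(c(1, f)))
  bad <- Mod(r) >= 1
  if (!any(bad)) return(f)
  r[bad] <- margin / Conj(r[bad])
  co <- 1
  for (root in r) co <- c(co, 0) - c(0, root * co)  # expand prod (x - r_i)
  Re(co[-1])
}

make_nl <- function(family, x, n_breakpoints, degree) {
  if (family == "identity") return(static_nl("identity"))
  if (family == "polynomial") {
    co <- numeric(degree + 1L); co[2] <- 1  # start from identity
    return(static_nl("polynomial", coefficients = co))
  }
  r <- range(x)
  if (diff(r) <= 0) stop("identify_hw: degenerate (constant) signal")
  bp <- seq(r[1], r[2], length.out = n_breakpoints)
  static_nl("piecewise_linear", breakpoints = bp, values = bp)
}

# Regression basis of a nonlinearity's free parameters evaluated at x:
# columns are d f(x) / d par_m (both families are linear in their
# parameters).
nl_basis <- function(nl, x) {
  switch(nl$family,
    piecewise_linear = pwl_basis(nl$breakpoints, x),
    polynomial = outer(x, seq_along(nl$coefficients) - 1L, `^`),
    stop("nl_basis: identity has no parameters")
  )
}

# Ridge-stabilised least squares; basis columns for unvisited piecewise
# segments can be all-zero, so plain solve() may be singular.
ls_solve <- function(X, t, ridge = 1e-9) {
  A <- crossprod(X) + diag(ridge, ncol(X))
  as.numeric(solve(A, crossprod(X, t)))
}

# Fix the gain/offset ambiguity between the input nonlinearity and the
# linear block: f(0) = 0 and unit mean slope over the breakpoint span, with
# the scale folded into b.
normalise_input_nl <- function(nl, b) {
  par <- nl_get_par(nl)
  f0 <- eval_nl(nl, 0)
  if (nl$family == "piecewise_linear") {
    par <- par - f0
    nl <- nl_set_par(nl, par)
    span <- nl$breakpoints[length(nl$breakpoints)] - nl$breakpoints[1]
    s <- (par[length(par)] - par[1]) / span
  } else {  # polynomial
    par[1] <- par[1] - f0
    nl <- nl_set_par(nl, par)
    s <- par[2]
  }
  if (is.finite(s) && abs(s) > 1e-9) {
    nl <- nl_set_par(nl, nl_get_par(nl) / s)
    b <- b * s
  }
  list(nl = nl, b = b)
}

# Invertible (non-decreasing, strictly increasing after projection) output
# map for the equation-error target v = h^{-1}(y).
invert_output_nl <- function(nl, y) {
  if (nl$family == "identity") return(y)
  if (nl$family != "piecewise_linear")
    stop("identify_hw: only identity or piecewise_linear output blocks are ",
         "supported for identification")
  val <- nl$values
  val <- cummax(val)
  val <- val + seq_along(val) * 1e-9 * max(abs(val), 1)  # strict increase
  stats::approx(val, nl$breakpoints, xout = y, rule = 2)$y
}

#' Identify a Hammerstein-Wiener model from input/output data
#'
#' The model is not linear in its full parameter set, so identification
#' alternates: with the nonlinearity shapes frozen, the linear block is
#' linear-in-parameters and is estimated by recursive least squares; the
#' nonlinearity node values are then refit by linear least squares, and the
#' loop repeats until the packed parameter vector changes by less than `tol`
#' (relative) or `max_iter` outer iterations. The convergence flag reports
#' whether the RLS estimate settled (relative drift over the last 10% of
#' samples below `conv_tol`).
#'
#' @param u Input `signal_trace` (preprocessed EMG envelope).
#' @param y Output `signal_trace` (preprocessed force), same length as `u`.
#' @param config A [hw_config()].
#' @return A `hw_model` with `converged` flag and a `fit_info` element
#'   (outer iterations used, final RLS innovation RMS, trajectory summary).
#' @export
identify_hw <- function(u, y, config = hw_config()) {
  uv <- if (inherits(u, "signal_trace")) u$samples else as.numeric(u)
  yv <- if (inherits(y, "signal_trace")) y$samples else as.numeric(y)
  if (length(uv) != length(yv)) stop("identify_hw: u and y lengths differ")
  if (diff(range(uv)) <= 0) stop("identify_hw: degenerate (constant) input")
  n <- length(uv)
  p_lin <- config$nb + config$nf
  if (n < 10L * p_lin)
    stop("identify_hw: need at least 10 x (nb + nf) = ", 10L * p_lin,
         " samples, got ", n)

  input_nl <- make_nl(config$input_family, uv, config$n_breakpoints,
                      config$degree)
  output_nl <- make_nl(config$output_family, yv, config$n_breakpoints,
                       config$degree)
  orders <- list(nb = config$nb, nf = config$nf, nk = config$nk)
  kmin <- max(config$nb + config$nk, config$nf + 1L)
  ks <- kmin:n
  block <- linear_block(b = c(1, numeric(config$nb - 1L)),
                        f = numeric(config$nf), nk = config$nk)
  model <- hw_model(input_nl, block, output_nl)
  theta_prev <- hw_pack_theta(model)
  v <- invert_output_nl(model$output_nl, yv)
  fit <- NULL

  have_model <- FALSE
  for (iter in seq_len(config$max_iter)) {
    ## linear stage by RLS, nonlinearities frozen; from the second iteration
    ## onwards the output lags can come from the model's own simulation
    ## (output-error pseudolinear regression) instead of the measured output
    w <- eval_nl(model$input_nl, uv)
    y_reg <- if (config$sim_regressor && have_model)
      linear_sim(model$linear, w) else v
    Phi <- matrix(0, length(ks), p_lin)
    for (r in seq_along(ks))
      Phi[r, ] <- build_regressor(w, y_reg, ks[r], orders)
    fit <- rls_run(Phi, v[ks], p0_scale = config$p0_scale,
                   trace_every = max(1L, length(ks) %/% 200L))
    th <- fit$state$theta_hat
    model$linear$b <- th[seq_len(config$nb)]
    model$linear$f <- if (config$nf > 0L) th[config$nb + seq_len(config$nf)]
                      else numeric(0)
    if (config$enforce_stability)
      model$linear$f <- stabilise_f(model$linear$f)
    have_model <- TRUE

    ## refit input nonlinearity node values (linear LS given b, f)
    if (model$input_nl$family != "identity") {
      B <- nl_basis(model$input_nl, uv)
      X <- matrix(0, length(ks), ncol(B))
      for (j in seq_len(config$nb)) {
        lag <- config$nk + j - 1L
        X <- X + model$linear$b[j] * B[ks - lag, , drop = FALSE]
      }
      tgt <- v[ks]
      if (config$nf > 0L)
        for (j in seq_len(config$nf))
          tgt <- tgt + model$linear$f[j] * y_reg[ks - j]
      par <- ls_solve(X, tgt)
      model$input_nl <- nl_set_par(model$input_nl, par)
      nb_fix <- normalise_input_nl(model$input_nl, model$linear$b)
      model$input_nl <- nb_fix$nl
      model$linear$b <- nb_fix$b
    }

    ## refit output nonlinearity against the linear-stage simulation
    if (model$output_nl$family != "identity") {
      w <- eval_nl(model$input_nl, uv)
      ylin <- linear_sim(model$linear, w)
      r <- range(ylin)
      if (diff(r) > 0) {
        bp <- seq(r[1], r[2], length.out = config$n_breakpoints)
        model$output_nl <- static_nl("piecewise_linear", breakpoints = bp,
                                     values = bp)
        B <- nl_basis(model$output_nl, ylin)
        par <- ls_solve(B[ks, , drop = FALSE], yv[ks])
        model$output_nl <- nl_set_par(model$output_nl, par)
        v <- invert_output_nl(model$output_nl, yv)
      }
    }

    ## keep the iterate that simulates the training data best (the
    ## alternating scheme is not monotone in simulation fit)
    y_sim <- tryCatch(simulate_hw(model, uv)$samples,
                      error = function(e) NULL)
    sim_rmse <- if (is.null(y_sim)) Inf
                else sqrt(mean((yv[ks] - y_sim[ks])^2))
    if (iter == 1L || sim_rmse < best_rmse) {
      best_rmse <- sim_rmse
      best_model <- model
      best_fit <- fit
    }

    theta_now <- hw_pack_theta(model)
    if (length(theta_now) == length(theta_prev)) {
      rel <- sqrt(sum((theta_now - theta_prev)^2)) /
        max(sqrt(sum(theta_now^2)), .Machine$double.eps)
      if (rel < config$tol) { theta_prev <- theta_now; break }
    }
    theta_prev <- theta_now
  }
  model <- best_model
  fit <- best_fit

  model$converged <- isTRUE(rls_converged(fit$trajectory,
                                          tol = config$conv_tol))
  if (!block_is_stable(model$linear))
    warning("identify_hw: identified linear block is unstable")
  model$fit_info <- list(
    outer_iters = iter,
    innovation_rms = sqrt(mean(fit$state$eps^2)),
    theta_lin_final = fit$state$theta_hat,
    rls_steps = max(attr(fit$trajectory, "steps")),
    config = config
  )
  model
}
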