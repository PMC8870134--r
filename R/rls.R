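#' Initialise a recursive-least-squares state
#'
#' theta starts at zero and the adaptation matrix at `p0_scale` times the
#' identity; with these choices the RLS trajectory ends exactly at the batch
#' regularised least-squares solution with prior precision `P0^-1`.
#'
#' @param p Number of parameters (>= 1).
#' @param p0_scale Initial adaptation-matrix scale (> 0, default 1e4).
#' @return An `rls_state` with fields `theta_hat`, `P`, `eps`, `k`.
#' @export
rls_init <- function(p, p0_scale = 1e4) {
  p <- as.integer(p)
  if (p < 1L) stop("rls_init: p must be >= 1")
  if (!is.finite(p0_scale) || p0_scale <= 0)
    stop("rls_init: p0_scale must be > 0")
  structure(list(theta_hat = numeric(p), P = diag(p0_scale, p),
                 eps = NA_real_, k = 0L),
            class = "rls_state")
}

#' One recursive-least-squares update
#'
#' Innovation eps(k) = y(k) - theta_hat(k-1)' phi(k); adaptation matrix
#' P(k) = P(k-1) - P(k-1) phi phi' P(k-1) / (1 + phi' P(k-1) phi); estimate
#' theta_hat(k) = theta_hat(k-1) + P(k) phi eps(k). No forgetting factor
#' (lambda = 1). P is re-symmetrised after every update.
#'
#' @param state An `rls_state`.
#' @param phi Regression vector (length p).
#' @param y Scalar observation.
#' @return The updated `rls_state`.
#' @export
rls_update <- function(state, phi, y) {
  stopifnot(inherits(state, "rls_state"))
  phi <- as.numeric(phi)
  if (length(phi) != length(state$theta_hat))
    stop("rls_update: phi length does not match state dimension")
  if (!all(is.finite(phi)) || !is.finite(y))
    stop("rls_update: non-finite input")
  P <- state$P
  Pphi <- P %*% phi
  denom <- 1 + sum(phi * Pphi)
  P <- P - tcrossprod(Pphi) / denom
  P <- (P + t(P)) / 2
  eps <- y - sum(state$theta_hat * phi)
  state$theta_hat <- state$theta_hat + as.numeric(P %*% phi) * eps
  state$P <- P
  state$eps <- eps
  state$k <- state$k + 1L
  state
}

#' Run RLS over a dataset
#'
#' @param Phi Matrix of regression vectors (rows = time steps).
#' @param y Observation vector (length = nrow(Phi)).
#' @param p0_scale Initial adaptation scale, see [rls_init()].
#' @param trace_every Record the estimate every this many steps (0 = final
#'   only).
#' @return A list: `state` (final `rls_state`), `trajectory` (matrix of
#'   recorded estimates, one row per record, with attribute `steps`).
#' @export
rls_run <- function(Phi, y, p0_scale = 1e4, trace_every = 1L) {
  Phi <- as.matrix(Phi)
  n <- nrow(Phi)
  if (length(y) != n) stop("rls_run: y length must match nrow(Phi)")
  state <- rls_init(ncol(Phi), p0_scale)
  keep <- if (trace_every > 0L) seq(trace_every, n, by = trace_every) else n
  traj <- matrix(NA_real_, length(keep), ncol(Phi))
  ti <- 1L
  for (k in seq_len(n)) {
    state <- rls_update(state, Phi[k, ], y[k])
    if (ti <= length(keep) && k == keep[ti]) {
      traj[ti, ] <- state$theta_hat
      ti <- ti + 1L
    }
  }
  attr(traj, "steps") <- keep
  list(state = state, trajectory = traj)
}

# Did the estimate settle? Compares each recorded estimate in the last
# `window` fraction of steps against the final one.
rls_converged <- function(trajectory, window = 0.1, tol = 0.05) {
  steps <- attr(trajectory, "steps")
  n <- max(steps)
  final <- trajectory[nrow(trajectory), ]
  idx <- which(steps >= (1 - window) * n)
  if (length(idx) < 2L) return(NA)
  ref <- max(sqrt(sum(final^2)), .Machine$double.eps)
  dev <- apply(trajectory[idx, , drop = FALSE], 1,
               function(th) sqrt(sum((th - final)^2)))
  max(dev) / ref < tol
}
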