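#' Sub-model library
#'
#' The model base of the multimodel estimator: N Hammerstein-Wiener
#' sub-models, each identified on one (EMG, force) measurement couple.
#'
#' @param entries List of entries, each a list with fields `id` (integer),
#'   `model` (a `hw_model`), `training_ref` (identifier of the training
#'   couple) and `profile_kind` (optional).
#' @param fs Sampling rate the library's signals live at (Hz).
#' @return A `model_library` object.
#' @export
model_library <- function(entries, fs = NA_real_) {
  if (length(entries) < 1L) stop("model_library: need at least one entry")
  ids <- vapply(entries, function(e) as.integer(e$id), integer(1))
  if (anyDuplicated(ids)) stop("model_library: entry ids must be unique")
  for (e in entries)
    if (!inherits(e$model, "hw_model"))
      stop("model_library: every entry needs a hw_model in $model")
  structure(list(entries = entries, fs = fs), class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat(sprintf("<model_library: %d sub-models>\n", length(x$entries)))
  for (e in x$entries)
    cat(sprintf("  [%d] %s (trained on %s)\n", e$id,
                e$model$input_nl$family,
                if (is.null(e$training_ref)) "?" else e$training_ref))
  invisible(x)
}

#' Number of sub-models in a library
#' @param library A `model_library`.
#' @return Integer N.
#' @export
library_size <- function(library) length(library$entries)

library_warmup <- function(library)
  max(vapply(library$entries, function(e) hw_warmup(e$model), numeric(1)))

#' Simulate every sub-model on every multimodel input channel
#'
#' @param library A `model_library` of N sub-models.
#' @param emg List of J preprocessed EMG `signal_trace`s (the multimodel
#'   inputs).
#' @return N x J matrix of sample vectors, as a list-matrix; element
#'   `[i, j]` is sub-model i driven by input channel j.
#' @export
run_submodels <- function(library, emg) {
  if (inherits(emg, "signal_trace")) emg <- list(emg)
  N <- library_size(library)
  J <- length(emg)
  out <- vector("list", N * J)
  dim(out) <- c(N, J)
  for (i in seq_len(N))
    for (j in seq_len(J))
      out[[i, j]] <- simulate_hw(library$entries[[i]]$model, emg[[j]])$samples
  out
}

#' Residues of sub-model outputs against a reference
#'
#' err\[i, j, k\] = |F_ij(k) - F_j(k)|: the absolute deviation of sub-model
#' i's output on channel j from the reference force of channel j. An
#' optional centred moving average (window in samples) stabilises the
#' residues under noisy references.
#'
#' @param F_ij List-matrix from [run_submodels()].
#' @param reference List of J reference force traces (numeric vectors or
#'   `signal_trace`s). Mandatory: the decision unit cannot run
#'   reference-free.
#' @param smooth_window Moving-average window in samples (default 1 = off).
#' @return Numeric array err of dimension N x J x K.
#' @export
compute_residues <- function(F_ij, reference, smooth_window = 1L) {
  if (is.null(reference)) stop("compute_residues: reference is mandatory")
  if (!is.list(reference) || inherits(reference, "signal_trace"))
    reference <- list(reference)
  ref <- lapply(reference, function(r)
    if (inherits(r, "signal_trace")) r$samples else as.numeric(r))
  N <- nrow(F_ij); J <- ncol(F_ij)
  if (length(ref) != J)
    stop("compute_residues: need one reference per input channel")
  K <- length(F_ij[[1, 1]])
  err <- array(0, c(N, J, K))
  for (i in seq_len(N))
    for (j in seq_len(J)) {
      if (length(F_ij[[i, j]]) != length(ref[[j]]))
        stop("compute_residues: trace lengths differ")
      e <- abs(F_ij[[i, j]] - ref[[j]])
      if (smooth_window > 1L) {
        kern <- rep(1 / smooth_window, smooth_window)
        e <- as.numeric(stats::filter(e, kern, sides = 2))
        e[is.na(e)] <- abs(F_ij[[i, j]] - ref[[j]])[is.na(e)]
      }
      err[i, j, ] <- e
    }
  err
}

#' Normalise residues across the sub-model axis
#'
#' err'\[i\] = err\[i\] / sum_i err\[i\] per (channel, time step); when the
#' residues sum to at most `tie_eps` (several simultaneously perfect
#' sub-models) the tie rule assigns 1/N to each.
#'
#' @param err N x J x K residue array (or a bare vector over i for one
#'   (j, k)).
#' @param tie_eps Degenerate-sum threshold (default 1e-12).
#' @return Array of the same shape with unit sums over i.
#' @export
normalize_residues <- function(err, tie_eps = 1e-12) {
  vec_in <- is.null(dim(err))
  if (vec_in) err <- array(err, c(length(err), 1L, 1L))
  N <- dim(err)[1]
  if (N < 2L) stop("normalize_residues: need N >= 2 sub-models")
  s <- apply(err, c(2, 3), sum)
  out <- err
  for (i in seq_len(N)) out[i, , ] <- err[i, , ] / s
  tie <- s <= tie_eps
  if (any(tie)) for (i in seq_len(N)) {
    sl <- out[i, , , drop = FALSE]
    sl[array(tie, dim(sl))] <- 1 / N
    out[i, , ] <- sl
  }
  if (vec_in) as.numeric(out) else out
}

#' Validity coefficients from normalised residues
#'
#' mu\[i\] = 1 - err'\[i\]: validities lie in \[0, 1\], vary contrary to the
#' residues (the most pertinent sub-model has the smallest residue and the
#' largest validity), and sum to N - 1 over the sub-model axis.
#'
#' @param err_norm Normalised residue array from [normalize_residues()].
#' @return Array (same shape) of validities.
#' @export
compute_validities <- function(err_norm) 1 - err_norm

#' Fusion weights from validities
#'
#' Three modes:
#' * `normalised` (default): w_i = mu_i / sum_i mu_i, so the weights are a
#'   convex combination (for N = 2 this coincides with `paper_literal`);
#' * `paper_literal`: w_i = mu_i used directly, which for N > 2 scales the
#'   fused output by up to N - 1;
#' * `switching`: winner-take-all on the largest validity.
#'
#' @param mu Validity array (N x J x K) or vector over i.
#' @param mode Weighting mode.
#' @return Weights, same shape as `mu`.
#' @export
fusion_weights <- function(mu, mode = c("normalised", "paper_literal",
                                        "switching")) {
  mode <- match.arg(mode)
  vec_in <- is.null(dim(mu))
  if (vec_in) mu <- array(mu, c(length(mu), 1L, 1L))
  N <- dim(mu)[1]
  if (any(mu < -1e-12 | mu > 1 + 1e-12))
    stop("fusion_weights: validities must lie in [0, 1]")
  w <- mu
  if (mode == "normalised") {
    s <- apply(mu, c(2, 3), sum)
    if (any(s <= 0))
      stop("fusion_weights: validities sum to zero (is N >= 2?)")
    for (i in seq_len(N)) w[i, , ] <- mu[i, , ] / s
  } else if (mode == "switching") {
    for (j in seq_len(dim(mu)[2]))
      for (k in seq_len(dim(mu)[3])) {
        best <- which.max(mu[, j, k])
        w[, j, k] <- 0
        w[best, j, k] <- 1
      }
  }
  if (vec_in) as.numeric(w) else w
}

#' Fuse sub-model outputs with time-varying weights
#'
#' F_m_j(k) = sum_i w\[i, j, k\] F_ij(k). With convex weights the fused
#' output lies within the per-step envelope of the sub-model outputs.
#'
#' @param F_ij List-matrix from [run_submodels()].
#' @param w Weight array (N x J x K).
#' @return List of J fused sample vectors.
#' @export
fuse_outputs <- function(F_ij, w) {
  N <- nrow(F_ij); J <- ncol(F_ij); K <- dim(w)[3]
  if (dim(w)[1] != N || dim(w)[2] != J)
    stop("fuse_outputs: weight dimensions do not match F_ij")
  out <- vector("list", J)
  for (j in seq_len(J)) {
    acc <- numeric(K)
    for (i in seq_len(N)) acc <- acc + w[i, j, ] * F_ij[[i, j]]
    out[[j]] <- acc
  }
  out
}

#' Multimodel force estimation
#'
#' The full decision chain: simulate every sub-model on every input channel,
#' compute residues against the reference forces, normalise them across the
#' library, derive validities, turn them into fusion weights, and fuse. The
#' first warm-up samples (max over the library) are dropped from the fused
#' outputs and the audit arrays.
#'
#' @param library A `model_library`.
#' @param emg List of J preprocessed EMG input traces.
#' @param reference List of J reference force traces (measured/desired).
#' @param mode Fusion mode, see [fusion_weights()].
#' @param smooth_window Residue smoothing window, see [compute_residues()].
#' @param tie_eps Tie threshold, see [normalize_residues()].
#' @return A `multimodel_output`: `F_m` (list of J fused `signal_trace`s),
#'   `validity` (list of arrays `err`, `err_norm`, `mu`, `w`, each
#'   N x J x K'), `F_ij` (trimmed sub-model outputs), `warmup`, `mode`.
#' @export
mm_estimate <- function(library, emg, reference,
                        mode = c("normalised", "paper_literal", "switching"),
                        smooth_window = 1L, tie_eps = 1e-12) {
  mode <- match.arg(mode)
  if (inherits(emg, "signal_trace")) emg <- list(emg)
  if (is.null(reference)) stop("mm_estimate: reference forces are mandatory")
  if (inherits(reference, "signal_trace")) reference <- list(reference)
  fs <- emg[[1]]$fs
  F_ij <- run_submodels(library, emg)
  err <- compute_residues(F_ij, reference, smooth_window = smooth_window)
  warm <- library_warmup(library)
  K <- dim(err)[3]
  keep <- (warm + 1L):K
  F_ij_t <- F_ij
  for (i in seq_len(nrow(F_ij)))
    for (j in seq_len(ncol(F_ij)))
      F_ij_t[[i, j]] <- F_ij[[i, j]][keep]
  err <- err[, , keep, drop = FALSE]
  err_norm <- normalize_residues(err, tie_eps = tie_eps)
  mu <- compute_validities(err_norm)
  w <- fusion_weights(mu, mode = mode)
  fused <- fuse_outputs(F_ij_t, w)
  F_m <- lapply(seq_along(fused), function(j)
    signal_trace(fused[[j]], fs = fs, label = paste0("F_m", j),
                 kind = "normalised"))
  structure(list(F_m = F_m,
                 validity = list(err = err, err_norm = err_norm,
                                 mu = mu, w = w),
                 F_ij = F_ij_t, warmup = warm, mode = mode),
            class = "multimodel_output")
}
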