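#' Butterworth filter specification
#'
#' @param order Filter order (positive integer; default 6).
#' @param cutoff_hz Cutoff frequency in Hz (default 1).
#' @param mode `"zero_phase"` (forward-backward, the default for offline
#'   analysis) or `"causal"` (single forward pass, for online use).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 6L, cutoff_hz = 1.0,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  order <- as.integer(order)
  if (order < 1L) stop("filter_spec: order must be >= 1")
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0)
    stop("filter_spec: cutoff_hz must be > 0")
  structure(list(order = order, cutoff_hz = cutoff_hz, mode = mode),
            class = "filter_spec")
}

# Butterworth design as cascaded second-order sections via the bilinear
# transform. A single transfer-function realisation is numerically
# untrustworthy at cutoff/fs ratios as small as 1/1000 (the envelope filter's
# operating point); the SOS cascade keeps each section well conditioned.
# Each section is rescaled so its passband reference gain (DC for lowpass,
# Nyquist for highpass) is exactly 1 in floating point.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz >= fs / 2)
    stop("butter_sos: cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         fs / 2, " Hz)")
  W <- tan(pi * cutoff_hz / fs)  # prewarped analog cutoff
  sections <- list()
  for (k in seq_len(order %/% 2)) {
    theta <- pi * (2 * k + order - 1) / (2 * order)
    as_ <- -2 * cos(theta)  # prototype pole pair at exp(+-i*theta), Re < 0
    if (type == "low") {
      a0 <- 1 + as_ * W + W^2
      a <- c(1, (2 * W^2 - 2) / a0, (1 - as_ * W + W^2) / a0)
      b <- (W^2 / a0) * c(1, 2, 1)
      b <- b * (sum(a) / sum(b))
    } else {
      a0 <- 1 + as_ * W + W^2
      a <- c(1, (2 * W^2 - 2) / a0, (1 - as_ * W + W^2) / a0)
      b <- (1 / a0) * c(1, -2, 1)
      b <- b * ((a[1] - a[2] + a[3]) / (b[1] - b[2] + b[3]))
    }
    sections[[length(sections) + 1L]] <- list(b = b, a = a)
  }
  if (order %% 2 == 1) {
    if (type == "low") {
      a0 <- 1 + W
      a <- c(1, (W - 1) / a0, 0)
      b <- (W / a0) * c(1, 1, 0)
      b <- b * (sum(a) / sum(b))
    } else {
      a0 <- 1 + W
      a <- c(1, (W - 1) / a0, 0)
      b <- (1 / a0) * c(1, -1, 0)
      b <- b * ((a[1] - a[2]) / (b[1] - b[2]))
    }
    sections[[length(sections) + 1L]] <- list(b = b, a = a)
  }
  sections
}

# Direct-form II transposed biquad with explicit initial state.
biquad_filter <- function(x, b, a, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; a1 <- a[2]; a2 <- a[3]
  for (i in seq_len(n)) {
    y[i] <- b0 * x[i] + z1
    z1 <- b1 * x[i] - a1 * y[i] + z2
    z2 <- b2 * x[i] - a2 * y[i]
  }
  y
}

# Steady-state DF2T state for a constant input x0: with this initialisation a
# constant input produces a constant output (x0 * DC gain) from sample one.
biquad_zi_step <- function(b, a, x0) {
  g <- sum(b) / sum(a)
  x0 * c(g - b[1], b[3] - a[3] * g)
}

sos_filter_causal <- function(x, sections) {
  for (s in sections) x <- biquad_filter(x, s$b, s$a)
  x
}

# Zero-phase filtering: odd-reflection padding at both ends plus per-section
# steady-state initial conditions, forward then backward.
sos_filtfilt <- function(x, sections, npad) {
  n <- length(x)
  npad <- min(n - 1L, as.integer(npad))
  if (npad > 0L) {
    xp <- c(2 * x[1] - x[(npad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  } else {
    xp <- x
  }
  for (s in sections)
    xp <- biquad_filter(xp, s$b, s$a, biquad_zi_step(s$b, s$a, xp[1]))
  xp <- rev(xp)
  for (s in sections)
    xp <- biquad_filter(xp, s$b, s$a, biquad_zi_step(s$b, s$a, xp[1]))
  rev(xp)[(npad + 1L):(npad + n)]
}

#' Analytic Butterworth magnitude response
#'
#' |H(f)| = 1 / sqrt(1 + (f / fc)^(2 n)) for a lowpass of order n and cutoff
#' fc. Used as the reference when checking the implemented filter.
#'
#' @param f Frequency or frequencies in Hz.
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @return Magnitude response in (0, 1].
#' @export
butterworth_gain <- function(f, order, cutoff_hz) {
  1 / sqrt(1 + (f / cutoff_hz)^(2 * order))
}

#' Low-pass envelope extraction
#'
#' Applies the Butterworth lowpass described by `spec` to a (typically
#' rectified) trace. Zero-phase mode filters forward and backward, giving no
#' group delay and squaring the magnitude response; causal mode is a single
#' forward pass. DC gain is unity, so the envelope preserves the mean level.
#'
#' @param trace A `signal_trace` (rectified EMG or force).
#' @param spec A [filter_spec()]; cutoff must be below Nyquist.
#' @return A `signal_trace`; kind becomes `emg_envelope` for EMG input,
#'   otherwise the kind is kept.
#' @export
lowpass_envelope <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= trace$fs / 2)
    stop("lowpass_envelope: cutoff (", spec$cutoff_hz,
         " Hz) must be below Nyquist (", trace$fs / 2, " Hz)")
  n <- length(trace$samples)
  min_len <- 3L * (spec$order + 1L)
  if (n < min_len)
    stop("lowpass_envelope: trace too short (", n, " samples) for an order-",
         spec$order, " filter; need at least ", min_len)
  sections <- butter_sos(spec$order, spec$cutoff_hz, trace$fs, "low")
  y <- if (spec$mode == "zero_phase") {
    # pad over several filter time constants so edge transients die out
    sos_filtfilt(trace$samples, sections,
                 npad = ceiling(3 * trace$fs / spec$cutoff_hz))
  } else {
    sos_filter_causal(trace$samples, sections)
  }
  kind <- if (trace$kind %in% c("emg_raw", "emg_envelope")) "emg_envelope"
          else trace$kind
  as_trace_like(trace, y, kind = kind)
}

#' Preprocess EMG and force traces for model identification
#'
#' The standard chain applied per channel, channels never mixed: full-wave
#' rectification, Butterworth envelope extraction, then min-max normalisation.
#' When `params` is supplied (normalisation fitted on training data), it is
#' reused unchanged, so validation values may fall outside \[0, 1\]; they are
#' not clipped.
#'
#' @param emg List of raw EMG `signal_trace`s (same fs and length).
#' @param force List of force `signal_trace`s (same fs and length as the EMG).
#' @param spec A [filter_spec()].
#' @param params Optional list of `minmax_params` named as
#'   `list(emg = ..., force = ...)` from a previous call; when `NULL`,
#'   parameters are fitted on the given traces.
#' @return A list with elements `emg` (envelope traces, normalised), `force`
#'   (smoothed normalised force), and `params`.
#' @export
preprocess <- function(emg, force, spec = filter_spec(), params = NULL) {
  if (inherits(emg, "signal_trace")) emg <- list(emg)
  if (inherits(force, "signal_trace")) force <- list(force)
  all_traces <- c(emg, force)
  fs <- vapply(all_traces, function(t) t$fs, numeric(1))
  len <- vapply(all_traces, function(t) length(t$samples), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(len)) != 1L)
    stop("preprocess: all traces must share fs and length")

  chain <- function(trace) lowpass_envelope(rectify(trace), spec)
  emg_env <- lapply(emg, chain)
  force_sm <- lapply(force, chain)

  if (is.null(params)) {
    params <- list(emg = lapply(emg_env, minmax_fit),
                   force = lapply(force_sm, minmax_fit))
  }
  list(
    emg = mapply(minmax_apply, emg_env, params$emg, SIMPLIFY = FALSE),
    force = mapply(minmax_apply, force_sm, params$force, SIMPLIFY = FALSE),
    params = params
  )
}

#' Decimate a trace by an integer factor
#'
#' Plain subsampling, intended for envelope-domain signals whose content is
#' far below the decimated Nyquist rate (the 1 Hz envelope at 1000 Hz is
#' heavily oversampled; identification does not need it).
#'
#' @param trace A `signal_trace`.
#' @param factor Positive integer decimation factor.
#' @return The decimated `signal_trace` with fs divided by `factor`.
#' @export
decimate_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "signal_trace"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimate_trace: factor must be >= 1")
  if (factor == 1L) return(trace)
  idx <- seq(1L, length(trace$samples), by = factor)
  signal_trace(trace$samples[idx], fs = trace$fs / factor,
               label = trace$label, kind = trace$kind)
}
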