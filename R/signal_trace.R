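#' Uniformly sampled signal trace
#'
#' The basic carrier for all signals in the package: a numeric vector of
#' samples together with its sampling rate, a channel label and a kind tag.
#' Raw EMG is in volts, force in newtons; after min-max normalisation the
#' samples are dimensionless.
#'
#' @param samples Numeric vector, finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name.
#' @param kind One of `"emg_raw"`, `"emg_envelope"`, `"force"`,
#'   `"normalised"`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs, label = "signal",
                         kind = c("emg_raw", "emg_envelope", "force",
                                  "normalised")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("signal_trace: 'samples' must have length >= 1")
  if (!all(is.finite(samples)))
    stop("signal_trace: 'samples' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal_trace: 'fs' must be a positive scalar")
  structure(
    list(samples = samples, fs = fs, label = as.character(label)[1L],
         kind = kind),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s' (%s): %d samples @ %g Hz, range [%g, %g]>\n",
              x$label, x$kind, length(x$samples), x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Duration of a trace in seconds
#' @param trace A `signal_trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs

#' Time axis of a trace
#' @param trace A `signal_trace`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_time <- function(trace) (seq_along(trace$samples) - 1L) / trace$fs

as_trace_like <- function(trace, samples, kind = trace$kind,
                          label = trace$label) {
  signal_trace(samples, fs = trace$fs, label = label, kind = kind)
}

#' Full-wave rectification
#'
#' Replaces every sample by its absolute value. Idempotent; sampling rate,
#' length and label are unchanged.
#'
#' @param trace A `signal_trace` of kind `emg_raw` or `force`.
#' @return The rectified `signal_trace` (same kind).
#' @export
rectify <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (!trace$kind %in% c("emg_raw", "force"))
    stop("rectify: expected a raw EMG or force trace, got kind '",
         trace$kind, "'")
  as_trace_like(trace, abs(trace$samples))
}

#' Fit min-max normalisation parameters
#'
#' Records the minimum and maximum of a trace so that other traces (typically
#' validation data) can be mapped onto the same dimensionless scale,
#' d_n = (d_r - d_min) / (d_max - d_min).
#'
#' @param trace A `signal_trace` with length >= 2.
#' @return A `minmax_params` object with fields `d_min`, `d_max`,
#'   `source_label`.
#' @export
minmax_fit <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  if (length(trace$samples) < 2L)
    stop("minmax_fit: need at least 2 samples")
  d_min <- min(trace$samples)
  d_max <- max(trace$samples)
  if (d_max <= d_min)
    stop("minmax_fit: degenerate range (d_max == d_min) for channel '",
         trace$label, "'")
  structure(list(d_min = d_min, d_max = d_max, source_label = trace$label),
            class = "minmax_params")
}

#' Apply min-max normalisation
#'
#' Values outside the fitted range (possible when training parameters are
#' reused on validation data) are passed through unclipped so that
#' [minmax_invert()] remains an exact inverse.
#'
#' @param trace A `signal_trace`.
#' @param params A `minmax_params` object from [minmax_fit()].
#' @return A `signal_trace` of kind `normalised`.
#' @export
minmax_apply <- function(trace, params) {
  stopifnot(inherits(trace, "signal_trace"), inherits(params, "minmax_params"))
  if (params$d_max <= params$d_min)
    stop("minmax_apply: degenerate parameters")
  x <- (trace$samples - params$d_min) / (params$d_max - params$d_min)
  as_trace_like(trace, x, kind = "normalised")
}

#' Invert min-max normalisation
#'
#' @param trace A normalised `signal_trace`.
#' @param params The `minmax_params` used to normalise it.
#' @param kind Kind tag to restore on the output (default `"force"`).
#' @return The de-normalised `signal_trace`.
#' @export
minmax_invert <- function(trace, params, kind = "force") {
  stopifnot(inherits(trace, "signal_trace"), inherits(params, "minmax_params"))
  if (params$d_max <= params$d_min)
    stop("minmax_invert: degenerate parameters")
  x <- trace$samples * (params$d_max - params$d_min) + params$d_min
  as_trace_like(trace, x, kind = kind)
}
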