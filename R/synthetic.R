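#' Force profile specification
#'
#' The five grip-force trajectories of the emulated experiment:
#' * `step`: staircase of five 10 N increments, 10 s per level (10-50 N);
#' * `saw`: two back-to-back linear ramps from 0 to the peak;
#' * `vol`: freely varying force, realised as a seeded smoothed random walk
#'   clipped to \[0, peak\];
#' * `single_level`: steady 50 N;
#' * `circle`: one slow half-cosine rise and fall over 10 s.
#'
#' @param kind Profile kind.
#' @param peak_n Peak force in newtons (default 50).
#' @param duration_s Duration in seconds; defaults to 50 s (10 s for
#'   `circle`).
#' @param fs Sampling rate in Hz (default 1000).
#' @return A `profile_spec` object.
#' @export
profile_spec <- function(kind = c("step", "saw", "vol", "single_level",
                                  "circle"),
                         peak_n = 50, duration_s = NULL, fs = 1000) {
  kind <- match.arg(kind)
  if (is.null(duration_s))
    duration_s <- if (kind == "circle") 10 else 50
  if (duration_s <= 0) stop("profile_spec: duration must be > 0")
  if (peak_n < 0) stop("profile_spec: amplitudes must be >= 0")
  structure(list(kind = kind, peak_n = peak_n, duration_s = duration_s,
                 fs = fs),
            class = "profile_spec")
}

#' Generate a force profile trace
#'
#' @param spec A [profile_spec()].
#' @param seed Seed for the `vol` profile's random walk (ignored by the
#'   deterministic profiles).
#' @return A `signal_trace` of kind `force` (newtons).
#' @export
gen_force_profile <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "profile_spec"))
  n <- round(spec$duration_s * spec$fs)
  if (n < 1L) stop("gen_force_profile: zero duration")
  t <- (seq_len(n) - 1L) / spec$fs
  f <- switch(spec$kind,
    step = {
      n_levels <- 5L
      level_len <- spec$duration_s / n_levels
      lev <- pmin(floor(t / level_len) + 1L, n_levels)
      lev * (spec$peak_n / n_levels)
    },
    saw = {
      half <- spec$duration_s / 2
      phase <- t %% half
      spec$peak_n * phase / half
    },
    single_level = rep(spec$peak_n, n),
    circle = spec$peak_n / 2 * (1 - cos(2 * pi * t / spec$duration_s)),
    vol = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      # random walk smoothed to sub-Hz wander, scaled into [0, peak]
      walk <- cumsum(stats::rnorm(n))
      sections <- butter_sos(2, 0.2, spec$fs, "low")
      sm <- sos_filtfilt(walk, sections, npad = min(n - 1L, spec$fs * 5L))
      r <- range(sm)
      if (diff(r) <= 0) rep(spec$peak_n / 2, n)
      else spec$peak_n * (sm - r[1]) / diff(r)
    }
  )
  signal_trace(f, fs = spec$fs, label = paste0("force_", spec$kind),
               kind = "force")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Muscle/electrode parameters for synthetic EMG
#'
#' The generated EMG is amplitude-modulated band-limited noise: a 20-500 Hz
#' carrier whose instantaneous amplitude is `gain * (F / f_max)^gamma`, the
#' simplest construction whose rectified-and-filtered envelope recovers a
#' monotone (and, for gamma != 1, nonlinear) function of force. Defaults
#' mimic three forearm channels (ECR, FDS, FCR) with distinct gains and
#' nonlinearity exponents.
#'
#' @param gain Per-channel amplitude gains (> 0).
#' @param gamma Per-channel nonlinearity exponents (> 0).
#' @param noise_floor Additive noise amplitude relative to unit carrier RMS.
#' @param band_hz Carrier band (lower, upper) in Hz; upper edges at or above
#'   Nyquist are realised as a pure highpass.
#' @param hysteresis First-order lag coefficient in \[0, 1) applied to the
#'   modulator (0 = off).
#' @param f_max_n Force scale in newtons used in the modulator.
#' @param labels Channel labels.
#' @return A `muscle_params` object.
#' @export
muscle_params <- function(gain = c(1.0, 0.8, 1.2),
                          gamma = c(0.8, 1.0, 1.3),
                          noise_floor = 0.02,
                          band_hz = c(20, 500),
                          hysteresis = 0,
                          f_max_n = 50,
                          labels = c("emg_ecr", "emg_fds", "emg_fcr")) {
  if (any(gain <= 0) || any(gamma <= 0))
    stop("muscle_params: gain and gamma must be > 0")
  if (band_hz[1] <= 0) stop("muscle_params: band must start above 0 Hz")
  if (hysteresis < 0 || hysteresis >= 1)
    stop("muscle_params: hysteresis must lie in [0, 1)")
  structure(list(gain = gain, gamma = gamma, noise_floor = noise_floor,
                 band_hz = band_hz, hysteresis = hysteresis,
                 f_max_n = f_max_n, labels = labels),
            class = "muscle_params")
}

#' Generate synthetic EMG channels from a force trace
#'
#' @param force A `signal_trace` of kind `force` (samples >= 0).
#' @param params A [muscle_params()].
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List of EMG `signal_trace`s (kind `emg_raw`), one per channel.
#' @export
gen_emg_from_force <- function(force, params = muscle_params(), seed = 1L) {
  stopifnot(inherits(force, "signal_trace"), inherits(params, "muscle_params"))
  n <- length(force$samples)
  if (n < 1L) stop("gen_emg_from_force: empty force trace")
  if (any(force$samples < -1e-9))
    stop("gen_emg_from_force: force must be non-negative")
  fs <- force$fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hp <- butter_sos(4, params$band_hz[1], fs, "high")
  lp <- if (params$band_hz[2] < fs / 2)
    butter_sos(4, params$band_hz[2], fs, "low") else NULL
  out <- vector("list", length(params$gain))
  for (ch in seq_along(params$gain)) {
    carrier <- sos_filter_causal(stats::rnorm(n), hp)
    if (!is.null(lp)) carrier <- sos_filter_causal(carrier, lp)
    carrier <- carrier / max(sqrt(mean(carrier^2)), .Machine$double.eps)
    m <- params$gain[ch] *
      (pmax(force$samples, 0) / params$f_max_n)^params$gamma[ch]
    if (params$hysteresis > 0) {
      a <- params$hysteresis
      m <- as.numeric(stats::filter((1 - a) * m, a, method = "recursive"))
    }
    emg <- m * carrier + params$noise_floor * stats::rnorm(n)
    out[[ch]] <- signal_trace(emg, fs = fs,
                              label = params$labels[ch], kind = "emg_raw")
  }
  out
}

#' Synthetic dataset configuration
#'
#' @param n_subjects Number of synthetic subjects (default 1).
#' @param profiles Profile kinds to generate (default all five).
#' @param n_trials Trials per subject x profile (default 4).
#' @param fs Sampling rate in Hz.
#' @param peak_n Peak force in newtons.
#' @param durations_s Named per-profile durations in seconds (optional).
#' @param muscle A [muscle_params()].
#' @param force_noise_sd Gaussian measurement noise on the recorded force in
#'   newtons (default 0.2, within the dynamometer accuracy class of
#'   +-0.6 N); also keeps steady profiles from having a degenerate min-max
#'   range.
#' @return A `dataset_config` object.
#' @export
dataset_config <- function(n_subjects = 1L,
                           profiles = c("step", "saw", "vol", "single_level",
                                        "circle"),
                           n_trials = 4L, fs = 1000, peak_n = 50,
                           durations_s = NULL,
                           muscle = muscle_params(),
                           force_noise_sd = 0.2) {
  structure(list(n_subjects = as.integer(n_subjects), profiles = profiles,
                 n_trials = as.integer(n_trials), fs = fs, peak_n = peak_n,
                 durations_s = durations_s, muscle = muscle,
                 force_noise_sd = force_noise_sd),
            class = "dataset_config")
}

#' Generate a synthetic EMG/force dataset
#'
#' Subjects x profiles x trials of paired EMG and force traces with known
#' generator parameters. Per-trial seeds are derived deterministically from
#' the master seed, so regeneration with the same seed is bit-identical.
#'
#' @param config A [dataset_config()].
#' @param seed Master seed (integer).
#' @return A `synthetic_dataset`: list with `trials` (each with `subject`,
#'   `profile`, `trial`, `seed`, `force`, `emg`), `config`, `seed`.
#' @export
gen_dataset <- function(config = dataset_config(), seed = 1L) {
  stopifnot(inherits(config, "dataset_config"))
  grid <- expand.grid(trial = seq_len(config$n_trials),
                      profile = config$profiles,
                      subject = seq_len(config$n_subjects),
                      stringsAsFactors = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  trials <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    kind <- grid$profile[r]
    dur <- if (!is.null(config$durations_s) &&
               !is.null(config$durations_s[[kind]]))
      config$durations_s[[kind]] else NULL
    spec <- profile_spec(kind, peak_n = config$peak_n, duration_s = dur,
                         fs = config$fs)
    s <- trial_seeds[r]
    force <- gen_force_profile(spec, seed = s)
    emg <- gen_emg_from_force(force, config$muscle, seed = s + 1L)
    if (config$force_noise_sd > 0) {
      set.seed(s + 2L)
      force$samples <- pmax(
        force$samples + stats::rnorm(length(force$samples),
                                     sd = config$force_noise_sd), 0)
    }
    force$label <- "force_n"
    trials[[r]] <- list(subject = grid$subject[r], profile = kind,
                        trial = grid$trial[r], seed = s,
                        force = force, emg = emg)
  }
  structure(list(trials = trials, config = config, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d trials (%d subject(s) x {%s} x %d)>\n",
              length(x$trials), x$config$n_subjects,
              paste(x$config$profiles, collapse = ", "), x$config$n_trials))
  invisible(x)
}

#' Select trials from a dataset
#'
#' @param dataset A `synthetic_dataset`.
#' @param profile Profile kind(s) to keep (NULL = all).
#' @param trial Trial number(s) to keep (NULL = all).
#' @param subject Subject number(s) to keep (NULL = all).
#' @return List of matching trial records.
#' @export
dataset_trials <- function(dataset, profile = NULL, trial = NULL,
                           subject = NULL) {
  keep <- vapply(dataset$trials, function(tr) {
    (is.null(profile) || tr$profile %in% profile) &&
      (is.null(trial) || tr$trial %in% trial) &&
      (is.null(subject) || tr$subject %in% subject)
  }, logical(1))
  dataset$trials[keep]
}

#' Write a dataset as per-trial CSV files plus a manifest
#'
#' Each trial becomes `trial_<subject>_<profile>_<n>.csv` with columns
#' `time_s`, one per EMG channel, and `force_n`; `manifest.csv` lists the
#' files with their profile kinds and seeds.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (tr in dataset$trials) {
    fname <- sprintf("trial_s%d_%s_%d.csv", tr$subject, tr$profile, tr$trial)
    df <- data.frame(time_s = trace_time(tr$force))
    for (e in tr$emg) df[[e$label]] <- e$samples
    df$force_n <- tr$force$samples
    utils::write.csv(df, file.path(dir, fname), row.names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      file = fname, subject = tr$subject, profile = tr$profile,
      trial = tr$trial, seed = tr$seed, fs = tr$force$fs,
      n_samples = length(tr$force$samples))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a trial CSV
#'
#' Expects a header row with a `time_s` first column and named channel
#' columns; the sampling rate is inferred from the time column.
#'
#' @param path CSV file path.
#' @param force_col Name of the force column (default `force_n`).
#' @return List with `emg` (list of `signal_trace`), `force`
#'   (`signal_trace`), `fs`.
#' @export
read_trial_csv <- function(path, force_col = "force_n") {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df))
    stop("read_trial_csv: first column must be 'time_s'")
  dt <- stats::median(diff(df$time_s))
  fs <- round(1 / dt)
  emg_cols <- setdiff(names(df), c("time_s", force_col))
  emg <- lapply(emg_cols, function(cn)
    signal_trace(df[[cn]], fs = fs, label = cn, kind = "emg_raw"))
  force <- if (force_col %in% names(df))
    signal_trace(df[[force_col]], fs = fs, label = force_col, kind = "force")
  else NULL
  list(emg = emg, force = force, fs = fs)
}
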