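#' Coefficient of determination
#'
#' R2 = 1 - SS_res / SS_tot; can be negative for estimates worse than the
#' mean.
#'
#' @param y Reference vector (or `signal_trace`).
#' @param yhat Estimate, same length.
#' @return Scalar R2.
#' @export
r_squared <- function(y, yhat) {
  if (inherits(y, "signal_trace")) y <- y$samples
  if (inherits(yhat, "signal_trace")) yhat <- yhat$samples
  if (length(y) != length(yhat)) stop("r_squared: lengths differ")
  if (length(y) < 2L) stop("r_squared: need at least 2 samples")
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("r_squared: constant reference (zero variance)")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#'
#' @param y Reference vector (or `signal_trace`).
#' @param yhat Estimate, same length.
#' @return Scalar RMSE (>= 0).
#' @export
rmse <- function(y, yhat) {
  if (inherits(y, "signal_trace")) y <- y$samples
  if (inherits(yhat, "signal_trace")) yhat <- yhat$samples
  if (length(y) != length(yhat)) stop("rmse: lengths differ")
  sqrt(mean((y - yhat)^2))
}

#' Scenario specification
#'
#' The three validation layouts:
#' * scenario 1: sub-models and test trial share the profile kind (distinct
#'   trials; e.g. step -> held-out step);
#' * scenario 2: two known-profile sub-models (step, circle) against an
#'   arbitrary target (vol);
#' * scenario 3: three known-profile sub-models (step, circle, saw) against
#'   the same arbitrary target.
#'
#' @param id Scenario number (1, 2 or 3).
#' @param library_profiles Override of the library profile kinds.
#' @param target_profile Override of the test profile kind.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(id, library_profiles = NULL,
                          target_profile = NULL) {
  id <- as.integer(id)
  if (!id %in% 1:3) stop("scenario_spec: id must be 1, 2 or 3")
  defaults <- list(
    `1` = list(library = c("step", "step", "step"), target = "step"),
    `2` = list(library = c("step", "circle"), target = "vol"),
    `3` = list(library = c("step", "circle", "saw"), target = "vol"))
  d <- defaults[[as.character(id)]]
  structure(list(id = id,
                 library_profiles = if (is.null(library_profiles)) d$library
                                    else library_profiles,
                 target_profile = if (is.null(target_profile)) d$target
                                  else target_profile),
            class = "scenario_spec")
}

#' Evaluation/run configuration for scenarios
#'
#' @param filter A [filter_spec()] for preprocessing.
#' @param hw A [hw_config()] for sub-model identification.
#' @param fusion_mode Fusion mode, see [fusion_weights()].
#' @param decim Envelope-domain decimation factor applied after filtering
#'   (default 10: 1000 Hz -> 100 Hz; the envelope band is < 1 Hz).
#' @param emg_channel EMG channel index driving the multimodel (SISO path).
#' @param ann_lags Lagged samples per channel for the ANN features.
#' @param ann Optional [mlp_config()] overrides as a list (e.g.
#'   `list(max_iter = 50)`).
#' @return An `eval_config` list.
#' @export
eval_config <- function(filter = filter_spec(), hw = hw_config(),
                        fusion_mode = "normalised", decim = 10L,
                        emg_channel = 1L, ann_lags = 2L, ann = list()) {
  structure(list(filter = filter, hw = hw, fusion_mode = fusion_mode,
                 decim = as.integer(decim),
                 emg_channel = as.integer(emg_channel),
                 ann_lags = as.integer(ann_lags), ann = ann),
            class = "eval_config")
}

# Preprocess one trial with frozen normalisation parameters, then decimate
# to the envelope-domain rate.
prep_trial <- function(trial, config, params) {
  pp <- preprocess(trial$emg, list(trial$force), spec = config$filter,
                   params = params)
  list(emg = lapply(pp$emg, decimate_trace, factor = config$decim),
       force = decimate_trace(pp$force[[1]], factor = config$decim))
}

# Fit normalisation parameters on pooled training trials (per channel), so
# training and test live on one frozen scale.
fit_norm_params <- function(trials, config) {
  n_ch <- length(trials[[1]]$emg)
  pool <- function(get_trace) {
    lapply(trials, function(tr) lowpass_envelope(rectify(get_trace(tr)),
                                                 config$filter))
  }
  emg_params <- lapply(seq_len(n_ch), function(ch) {
    envs <- pool(function(tr) tr$emg[[ch]])
    all_samples <- unlist(lapply(envs, function(e) e$samples))
    minmax_fit(signal_trace(all_samples, fs = envs[[1]]$fs,
                            label = envs[[1]]$label, kind = "emg_envelope"))
  })
  f_envs <- pool(function(tr) tr$force)
  all_f <- unlist(lapply(f_envs, function(e) e$samples))
  force_params <- minmax_fit(signal_trace(all_f, fs = f_envs[[1]]$fs,
                                          label = "force_n", kind = "force"))
  list(emg = emg_params, force = list(force_params))
}

# preprocess() wants one params entry per trace passed; adapt the pooled
# per-channel parameters to a single trial's channel list.
trial_params <- function(norm) list(emg = norm$emg, force = norm$force)

#' Run one validation scenario on a synthetic dataset
#'
#' Builds the scenario's library from training trials, then evaluates the
#' multimodel estimator and the ANN baseline on held-out trials that never
#' enter any sub-model's training data. Scenario 1 trains one sub-model on
#' each of the first three trials of the target profile and tests the
#' fourth; scenarios 2 and 3 train one sub-model per library profile (first
#' trial of each) and test every trial of the target profile. All
#' preprocessing parameters are fitted on training data only and frozen.
#'
#' @param dataset A `synthetic_dataset` containing the required profiles.
#' @param spec A [scenario_spec()] (or scenario id 1-3).
#' @param config An [eval_config()].
#' @param methods Character subset of `c("mm", "ann")`.
#' @param seed Seed for the ANN initialisation.
#' @return An `evaluation_report`: `runs` (data frame with method, scenario,
#'   run, r2, rmse), `aggregates`, `details` (library, per-run outputs).
#' @export
run_scenario <- function(dataset, spec, config = eval_config(),
                         methods = c("mm", "ann"), seed = 1L) {
  if (!inherits(spec, "scenario_spec")) spec <- scenario_spec(spec)
  subject <- 1L
  ## ---- choose training and test trials
  if (spec$id == 1L) {
    pool <- dataset_trials(dataset, profile = spec$target_profile,
                           subject = subject)
    if (length(pool) < 4L)
      stop("run_scenario: scenario 1 needs >= 4 trials of profile '",
           spec$target_profile, "', found ", length(pool))
    train_trials <- pool[1:3]
    test_trials <- pool[4]
  } else {
    train_trials <- lapply(spec$library_profiles, function(pk) {
      tt <- dataset_trials(dataset, profile = pk, subject = subject)
      if (length(tt) < 1L)
        stop("run_scenario: no trials of library profile '", pk, "'")
      tt[[1]]
    })
    test_trials <- dataset_trials(dataset, profile = spec$target_profile,
                                  subject = subject)
    if (length(test_trials) < 1L)
      stop("run_scenario: no trials of target profile '",
           spec$target_profile, "'")
  }
  train_ids <- vapply(train_trials, function(tr)
    paste(tr$profile, tr$trial, sep = "_"), character(1))
  test_ids <- vapply(test_trials, function(tr)
    paste(tr$profile, tr$trial, sep = "_"), character(1))
  if (length(intersect(train_ids, test_ids)) > 0L)
    stop("run_scenario: train/test trial overlap")

  ## ---- preprocessing, frozen on training data
  norm <- fit_norm_params(train_trials, config)
  prep_train <- lapply(train_trials, prep_trial, config = config,
                       params = trial_params(norm))
  prep_test <- lapply(test_trials, prep_trial, config = config,
                      params = trial_params(norm))

  ## ---- multimodel library
  ch <- config$emg_channel
  couples <- lapply(seq_along(prep_train), function(i)
    list(emg = prep_train[[i]]$emg[[ch]], force = prep_train[[i]]$force,
         id = train_ids[i], profile = train_trials[[i]]$profile))
  library <- build_library(couples, config = config$hw,
                           n_override = length(couples))

  runs <- list()
  details <- list(library = library, train_ids = train_ids,
                  test_ids = test_ids, mm = list(), ann = list())

  if ("mm" %in% methods) {
    for (ti in seq_along(prep_test)) {
      pt <- prep_test[[ti]]
      out <- mm_estimate(library, list(pt$emg[[ch]]), list(pt$force),
                         mode = config$fusion_mode)
      ref <- pt$force$samples[(out$warmup + 1L):length(pt$force$samples)]
      runs[[length(runs) + 1L]] <- data.frame(
        method = "mm", scenario = spec$id, run = test_ids[ti],
        r2 = r_squared(ref, out$F_m[[1]]$samples),
        rmse = rmse(ref, out$F_m[[1]]$samples))
      ## per-sub-model cross-applied metrics, for audit
      sub_r2 <- vapply(seq_len(library_size(library)), function(i)
        r_squared(ref, out$F_ij[[i, 1]]), numeric(1))
      details$mm[[test_ids[ti]]] <- list(output = out, sub_r2 = sub_r2)
    }
  }

  if ("ann" %in% methods) {
    ann_args <- utils::modifyList(
      list(n_inputs = length(prep_train[[1]]$emg) * (config$ann_lags + 1L),
           seed = seed),
      config$ann)
    cfg <- do.call(mlp_config, ann_args)
    Xs <- lapply(prep_train, function(pt) ann_features(pt$emg,
                                                       config$ann_lags))
    Ys <- lapply(seq_along(prep_train), function(i) {
      f <- prep_train[[i]]$force$samples
      f <- f[(attr(Xs[[i]], "offset") + 1L):length(f)]
      cbind(f, matrix(0, length(f), cfg$n_outputs - 1L))
    })
    X <- do.call(rbind, Xs)
    Y <- do.call(rbind, Ys)
    trained <- mlp_train_lm(mlp_init(cfg), X, Y)
    details$ann$history <- trained$history
    for (ti in seq_along(prep_test)) {
      pt <- prep_test[[ti]]
      est <- ann_estimate(trained$weights, pt$emg, n_force = 1L,
                          n_lags = config$ann_lags)[[1]]
      off <- attr(est, "offset")
      ref <- pt$force$samples[(off + 1L):length(pt$force$samples)]
      runs[[length(runs) + 1L]] <- data.frame(
        method = "ann", scenario = spec$id, run = test_ids[ti],
        r2 = r_squared(ref, est$samples),
        rmse = rmse(ref, est$samples))
    }
  }

  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$method), function(d)
    data.frame(method = d$method[1], scenario = spec$id,
               r2_mean = mean(d$r2), r2_min = min(d$r2), r2_max = max(d$r2),
               r2_sd = stats::sd(d$r2),
               rmse_mean = mean(d$rmse), rmse_min = min(d$rmse),
               rmse_max = max(d$rmse), rmse_sd = stats::sd(d$rmse))))
  rownames(agg) <- NULL
  structure(list(runs = runs, aggregates = agg, details = details,
                 spec = spec),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: scenario %d, %d runs>\n",
              x$spec$id, nrow(x$runs)))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Combine scenario reports into a comparison table
#'
#' Long-form rows (method x scenario x run) plus a wide summary with the
#' multimodel column before the ANN column per scenario.
#'
#' @param reports List of `evaluation_report`s.
#' @return List: `long` (data frame of all runs), `wide` (mean R2 and RMSE
#'   per scenario and method, mm before ann).
#' @export
compare_methods <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  long <- do.call(rbind, lapply(reports, function(r) r$runs))
  rownames(long) <- NULL
  scen <- sort(unique(long$scenario))
  wide <- data.frame(metric = c("r2_mean", "rmse_mean"))
  for (s in scen)
    for (m in c("mm", "ann")) {
      d <- long[long$scenario == s & long$method == m, ]
      col <- sprintf("scenario%d_%s", s, m)
      wide[[col]] <- if (nrow(d)) c(mean(d$r2), mean(d$rmse))
                     else c(NA_real_, NA_real_)
    }
  list(long = long, wide = wide)
}
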