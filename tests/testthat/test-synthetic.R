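test_that("force profiles match their definitions", {
  step <- gen_force_profile(profile_spec("step"))
  expect_equal(step$samples[25 * 1000], 30)        # third 10 s level
  expect_equal(sort(unique(step$samples)), c(10, 20, 30, 40, 50))
  expect_equal(trace_duration(step), 50)

  single <- gen_force_profile(profile_spec("single_level"))
  expect_true(all(single$samples == 50))

  circle <- gen_force_profile(profile_spec("circle"))
  expect_lt(circle$samples[1], 1e-9)
  expect_lt(circle$samples[length(circle$samples)], 1e-3)
  tmax <- trace_time(circle)[which.max(circle$samples)]
  expect_equal(tmax, 5, tolerance = 1e-2)
  expect_equal(max(circle$samples), 50, tolerance = 1e-6)

  saw <- gen_force_profile(profile_spec("saw"))
  # two back-to-back ramps: linear rise to the peak, reset at half time
  expect_equal(saw$samples[25 * 1000], 50, tolerance = 0.01)
  expect_lt(saw$samples[25 * 1000 + 10], 1)
  expect_equal(diff(saw$samples[1:1000]),
               rep(diff(saw$samples[1:2]), 999), tolerance = 1e-9)

  vol <- gen_force_profile(profile_spec("vol"), seed = 3)
  expect_true(all(vol$samples >= 0 & vol$samples <= 50))
  expect_identical(gen_force_profile(profile_spec("vol"), seed = 3)$samples,
                   vol$samples)
  expect_error(profile_spec("step", duration_s = 0), "duration")
})

test_that("synthetic EMG is amplitude-modulated band-limited noise", {
  force <- gen_force_profile(profile_spec("step"))
  params <- muscle_params()
  emg <- gen_emg_from_force(force, params, seed = 2)
  expect_length(emg, 3)

  # envelope recovers the modulator gain * (F / Fmax)^gamma (compared at the
  # envelope filter's own bandwidth)
  env <- lowpass_envelope(rectify(emg[[1]]), filter_spec())
  modu <- params$gain[1] * (force$samples / params$f_max_n)^params$gamma[1]
  modu_sm <- lowpass_envelope(signal_trace(modu, force$fs, kind = "force"),
                              filter_spec())
  expect_gt(cor(env$samples, modu_sm$samples), 0.95)

  # >= 95% of power within 20-500 Hz at fs = 1000
  ps <- spec.pgram(emg[[2]]$samples, plot = FALSE, taper = 0)
  f_hz <- ps$freq * emg[[2]]$fs
  in_band <- f_hz >= 20 & f_hz <= 500
  expect_gt(sum(ps$spec[in_band]) / sum(ps$spec), 0.95)

  # zero force and zero floor give zero EMG
  z <- gen_emg_from_force(
    signal_trace(rep(0, 1000), 1000, kind = "force"),
    muscle_params(noise_floor = 0), seed = 1)
  expect_true(all(z[[1]]$samples == 0))
})

test_that("doubling the gain doubles the envelope amplitude", {
  force <- gen_force_profile(profile_spec("step", duration_s = 20))
  e1 <- gen_emg_from_force(force, muscle_params(gain = c(1, 1, 1)), seed = 5)
  e2 <- gen_emg_from_force(force, muscle_params(gain = c(2, 2, 2)), seed = 5)
  env1 <- lowpass_envelope(rectify(e1[[1]]), filter_spec())
  env2 <- lowpass_envelope(rectify(e2[[1]]), filter_spec())
  expect_equal(mean(env2$samples) / mean(env1$samples), 2, tolerance = 0.05)
})

test_that("dataset generation is shaped and seeded as configured", {
  cfg <- dataset_config(profiles = c("step", "circle"), n_trials = 2L)
  ds1 <- gen_dataset(cfg, seed = 11)
  ds2 <- gen_dataset(cfg, seed = 11)
  expect_length(ds1$trials, 4)
  expect_length(ds1$trials[[1]]$emg, 3)
  # bit-identical regeneration
  for (i in seq_along(ds1$trials)) {
    expect_identical(ds1$trials[[i]]$force$samples,
                     ds2$trials[[i]]$force$samples)
    expect_identical(ds1$trials[[i]]$emg[[3]]$samples,
                     ds2$trials[[i]]$emg[[3]]$samples)
  }
  ds3 <- gen_dataset(cfg, seed = 12)
  expect_false(identical(ds1$trials[[1]]$emg[[1]]$samples,
                         ds3$trials[[1]]$emg[[1]]$samples))
})

test_that("envelope-force monotonicity holds per trial at default noise", {
  ds <- gen_dataset(dataset_config(profiles = c("step", "saw", "circle"),
                                   n_trials = 1L), seed = 21)
  for (tr in ds$trials) {
    env <- lowpass_envelope(rectify(tr$emg[[1]]), filter_spec())
    force_sm <- lowpass_envelope(rectify(tr$force), filter_spec())
    expect_gt(cor(env$samples, force_sm$samples, method = "spearman"), 0.9)
  }
})

test_that("CSV export writes one file per trial plus a manifest, reproducibly", {
  dir <- withr::local_tempdir()
  cfg <- dataset_config(profiles = "circle", n_trials = 2L)
  man <- write_dataset_csv(gen_dataset(cfg, seed = 3), dir)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_setequal(list.files(dir, pattern = "^trial_"), man$file)

  trial <- read_trial_csv(file.path(dir, man$file[1]))
  expect_equal(trial$fs, 1000)
  expect_length(trial$emg, 3)
  expect_equal(trial$emg[[1]]$label, "emg_ecr")
  expect_s3_class(trial$force, "signal_trace")

  dir2 <- withr::local_tempdir()
  write_dataset_csv(gen_dataset(cfg, seed = 3), dir2)
  f <- man$file[1]
  expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
})
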