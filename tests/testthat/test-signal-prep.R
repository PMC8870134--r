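test_that("rectification takes absolute values, preserves zeros and is idempotent", {
  tr <- signal_trace(c(-1, 2, -3), fs = 100, kind = "emg_raw")
  expect_equal(rectify(tr)$samples, c(1, 2, 3))
  z <- signal_trace(rep(0, 5), fs = 100, kind = "force")
  expect_equal(rectify(z)$samples, rep(0, 5))
  r1 <- rectify(tr)
  expect_identical(rectify(r1)$samples, r1$samples)
  expect_equal(r1$fs, tr$fs)
  expect_equal(length(r1), length(tr))
})

test_that("rectified sine has mean 2A/pi over many cycles", {
  A <- 2.5
  fs <- 1000
  t <- seq(0, 120, by = 1 / fs)   # 120 cycles at 1 Hz
  tr <- signal_trace(A * sin(2 * pi * t), fs = fs, kind = "emg_raw")
  expect_equal(mean(rectify(tr)$samples), 2 * A / pi, tolerance = 0.01)
})

test_that("signal_trace validates its invariants", {
  expect_error(signal_trace(numeric(0), 100), "length")
  expect_error(signal_trace(c(1, NA), 100), "finite")
  expect_error(signal_trace(1:3, -1), "positive")
  expect_error(rectify(signal_trace(1:3, 10, kind = "normalised")), "kind")
})

test_that("envelope filter has unit DC gain and strong 50 Hz attenuation", {
  fs <- 1000
  spec <- filter_spec(6, 1, "zero_phase")
  const <- signal_trace(rep(3.7, 5000), fs = fs, kind = "emg_raw")
  out <- lowpass_envelope(const, spec)
  expect_lt(max(abs(out$samples - 3.7)), 1e-6)
  expect_equal(out$kind, "emg_envelope")
  expect_equal(length(out), length(const))

  t <- seq(0, 5, by = 1 / fs)
  s50 <- signal_trace(sin(2 * pi * 50 * t), fs = fs, kind = "emg_raw")
  y <- lowpass_envelope(s50, spec)
  ratio <- sqrt(mean(y$samples^2)) / sqrt(mean(s50$samples^2))
  expect_lt(ratio, 1e-3)
  # analytic response is > 100 dB down; the measured ratio is limited by the
  # numeric floor of forward-backward filtering but still beats -100 dB
  analytic <- butterworth_gain(50, 6, 1)^2
  expect_lt(analytic, 10^(-100 / 20))
  expect_lt(ratio, 10^(-100 / 20))
})

test_that("causal mode reaches the DC level after the transient", {
  fs <- 1000
  const <- signal_trace(rep(1.25, 20000), fs = fs, kind = "force")
  y <- lowpass_envelope(const, filter_spec(6, 1, "causal"))
  expect_lt(abs(y$samples[20000] - 1.25), 1e-3)
  # causal output lags: early samples far from DC
  expect_gt(abs(y$samples[10] - 1.25), 0.5)
})

test_that("envelope tracks the modulator of amplitude-modulated noise", {
  fs <- 1000
  set.seed(11)
  t <- seq(0, 20, by = 1 / fs)
  modu <- 1 + 0.8 * sin(2 * pi * 0.1 * t)
  carrier <- rnorm(length(t))
  tr <- signal_trace(modu * carrier, fs = fs, kind = "emg_raw")
  env <- lowpass_envelope(rectify(tr), filter_spec(6, 1))
  expect_gt(cor(env$samples, modu), 0.95)
})

test_that("filter preconditions are enforced", {
  expect_error(lowpass_envelope(signal_trace(rnorm(100), 10),
                                filter_spec(6, 6)), "Nyquist")
  expect_error(lowpass_envelope(signal_trace(rnorm(5), 1000),
                                filter_spec(6, 1)), "too short")
})

test_that("min-max normalisation fits, applies, inverts and rejects degeneracy", {
  tr <- signal_trace(c(2, 4, 6), fs = 1, kind = "force")
  p <- minmax_fit(tr)
  expect_equal(p$d_min, 2)
  expect_equal(p$d_max, 6)
  expect_equal(minmax_apply(tr, p)$samples, c(0, 0.5, 1))
  expect_error(minmax_fit(signal_trace(rep(0, 3), 1, kind = "force")),
               "degenerate")

  set.seed(3)
  x <- signal_trace(rnorm(500, 10, 4), fs = 1, kind = "force")
  px <- minmax_fit(x)
  n <- minmax_apply(x, px)
  expect_equal(min(n$samples), 0)
  expect_equal(max(n$samples), 1)
  back <- minmax_invert(n, px)
  expect_lt(max(abs(back$samples - x$samples)), 1e-12)
})

test_that("out-of-range values under frozen parameters pass through unclipped", {
  p <- minmax_fit(signal_trace(c(0, 10), 1, kind = "force"))
  val <- signal_trace(c(-5, 15), 1, kind = "force")
  n <- minmax_apply(val, p)
  expect_equal(n$samples, c(-0.5, 1.5))
  expect_equal(minmax_invert(n, p)$samples, val$samples)
})

test_that("preprocess chains per channel and freezes training parameters", {
  fs <- 1000
  ds <- gen_dataset(dataset_config(profiles = "step", n_trials = 2L),
                    seed = 5)
  tr1 <- ds$trials[[1]]; tr2 <- ds$trials[[2]]
  pp <- preprocess(tr1$emg, list(tr1$force))
  expect_length(pp$emg, 3)
  expect_equal(min(pp$force[[1]]$samples), 0)
  expect_equal(max(pp$force[[1]]$samples), 1)
  # envelope roughly monotone with the force staircase
  expect_gt(cor(pp$emg[[1]]$samples, pp$force[[1]]$samples,
                method = "spearman"), 0.9)
  # frozen params applied to another trial: no refit, range may exceed [0,1]
  pp2 <- preprocess(tr2$emg, list(tr2$force), params = pp$params)
  expect_identical(pp2$params, pp$params)
  expect_error(preprocess(list(signal_trace(1, fs, kind = "emg_raw")),
                          list(signal_trace(1, fs, kind = "force"))),
               "too short")
})

test_that("mismatched fs or length is rejected", {
  a <- signal_trace(rnorm(100), 100, kind = "emg_raw")
  b <- signal_trace(rnorm(100), 200, kind = "force")
  expect_error(preprocess(list(a), list(b)), "share fs")
})

test_that("decimation keeps every factor-th sample and rescales fs", {
  tr <- signal_trace(1:100, fs = 100, kind = "normalised")
  d <- decimate_trace(tr, 10)
  expect_equal(d$fs, 10)
  expect_equal(d$samples, seq(1, 100, by = 10))
  expect_identical(decimate_trace(tr, 1), tr)
})
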