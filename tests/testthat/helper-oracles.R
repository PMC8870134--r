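# Independent oracles and small fixture generators shared across tests.

# Sample-by-sample Hammerstein-Wiener recursion, written directly from the
# difference equation (independent of linear_sim / stats::filter).
hw_oracle_sim <- function(model, u) {
  w <- eval_nl(model$input_nl, u)
  b <- model$linear$b; f <- model$linear$f; nk <- model$linear$nk
  y <- numeric(length(u))
  for (k in seq_along(u)) {
    acc <- 0
    for (j in seq_along(b)) {
      idx <- k - nk - j + 1L
      if (idx >= 1L) acc <- acc + b[j] * w[idx]
    }
    for (j in seq_along(f)) {
      idx <- k - j
      if (idx >= 1L) acc <- acc - f[j] * y[idx]
    }
    y[k] <- acc
  }
  eval_nl(model$output_nl, y)
}

# Random small stable Hammerstein-Wiener model (poles drawn inside the unit
# circle, polynomial or identity nonlinearities).
random_hw_model <- function() {
  nb <- sample(1:3, 1)
  nf <- sample(0:2, 1)
  nk <- sample(0:2, 1)
  b <- round(runif(nb, -1, 1), 3)
  b[1] <- b[1] + sign(b[1] + 1e-9) * 0.2   # keep leading coefficient away from 0
  f <- if (nf == 1) {
    -round(runif(1, -0.8, 0.8), 3)
  } else if (nf == 2) {
    p <- runif(2, -0.8, 0.8)               # real poles p1, p2
    c(-(p[1] + p[2]), p[1] * p[2])
  } else numeric(0)
  in_nl <- if (runif(1) < 0.5) static_nl("identity")
           else static_nl("polynomial", coefficients = round(runif(3, -0.5, 0.5), 3))
  out_nl <- if (runif(1) < 0.5) static_nl("identity")
            else static_nl("polynomial", coefficients = round(runif(3, -0.5, 0.5), 3))
  hw_model(in_nl, linear_block(b, f, nk), out_nl)
}

# Known generator used in identification-recovery tests: quadratic input
# nonlinearity, stable second-order linear block, identity output.
recovery_generator <- function() {
  hw_model(static_nl("polynomial", coefficients = c(0, 1, 0.5)),
           linear_block(c(0.6, 0.3), c(-0.5, 0.2), nk = 1))
}

# Smooth, range-covering excitation for identification tests.
recovery_input <- function(n, seed) {
  set.seed(seed)
  u <- cumsum(rnorm(n))
  (u - min(u)) / diff(range(u))
}

# Small synthetic dataset for end-to-end tests (full trial durations, the
# generator's defaults; only the profiles a test needs).
scenario_dataset <- function(seed, profiles = c("step", "circle", "saw", "vol")) {
  gen_dataset(dataset_config(profiles = profiles), seed = seed)
}

# Envelope-like traces from three distribution classes that differ in
# level, spread and shape (as distinct EMG behaviours do); between-class
# level separation far exceeds the within-class spread. Trials are long
# enough for stable sample skewness/kurtosis.
feature_trials <- function(n_per_group = 4, means = c(0.2, 0.5, 0.8),
                           sds = c(0.005, 0.02, 0.05),
                           shapes = c(50, 8, 2), n = 6000, seed = 1) {
  set.seed(seed)
  trials <- list()
  grp <- integer(0)
  for (g in seq_along(means)) {
    for (r in seq_len(n_per_group)) {
      noise <- (rgamma(n, shapes[g], 1) - shapes[g]) / sqrt(shapes[g])
      trials[[length(trials) + 1L]] <-
        signal_trace(means[g] + sds[g] * noise, fs = 100,
                     kind = "emg_envelope")
      grp <- c(grp, g)
    }
  }
  list(trials = trials, group = grp)
}
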