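test_that("trial statistics summarise each envelope deterministically", {
  ft <- feature_trials(seed = 2)
  st <- trial_statistics(ft$trials)
  expect_equal(nrow(st), 12)
  expect_true(all(st$q1 <= st$median & st$median <= st$q3))
  expect_true(all(st$iqr >= 0))
  expect_identical(st, trial_statistics(ft$trials))
  # medians ordered by the construction means
  med_by_group <- tapply(st$median, ft$group, mean)
  expect_true(all(diff(med_by_group) > 0))
})

test_that("constant trials have zero IQR and variance; scaling is homogeneous", {
  const <- signal_trace(rep(2, 50), 10, kind = "emg_envelope")
  st <- trial_statistics(list(const))
  expect_equal(st$iqr, 0)
  expect_equal(st$variance, 0)

  set.seed(7)
  x <- runif(200)
  a <- trial_statistics(list(signal_trace(x, 10, kind = "emg_envelope")))
  b <- trial_statistics(list(signal_trace(3 * x, 10, kind = "emg_envelope")))
  expect_equal(b$median, 3 * a$median)
  expect_equal(b$iqr, 3 * a$iqr)
  expect_equal(b$variance, 9 * a$variance)
})

test_that("three well-separated groups suggest three sub-models", {
  ft <- feature_trials(seed = 5)
  plan <- suggest_submodel_count(trial_statistics(ft$trials), seed = 5)
  expect_equal(plan$suggested_n, 3L)
  # assignment respects the construction groups
  expect_equal(length(unique(tapply(plan$assignment, ft$group,
                                    function(a) a[1]))), 3)
})

test_that("identical trials fall back to a single sub-model", {
  tr <- signal_trace(rep(c(0.2, 0.4), 50), 10, kind = "emg_envelope")
  trials <- list(tr, tr, tr, tr)
  plan <- suggest_submodel_count(trial_statistics(trials), seed = 1)
  expect_equal(plan$suggested_n, 1L)
})

test_that("suggestion is invariant to trial order", {
  ft <- feature_trials(seed = 9)
  st <- trial_statistics(ft$trials)
  plan1 <- suggest_submodel_count(st, seed = 3)
  set.seed(99)
  perm <- sample(nrow(st))
  plan2 <- suggest_submodel_count(st[perm, ], seed = 3)
  expect_equal(plan2$suggested_n, plan1$suggested_n)
})

test_that("cluster-count recovery succeeds in >= 95% of seeded runs", {
  hits <- 0L
  for (s in 1:100) {
    ft <- feature_trials(seed = s)  # class separation >> within-class spread
    plan <- suggest_submodel_count(trial_statistics(ft$trials), seed = s)
    hits <- hits + (plan$suggested_n == 3L)
  }
  expect_gte(hits, 95L)
})

test_that("too few trials are rejected", {
  ft <- feature_trials(n_per_group = 1, seed = 1)
  expect_error(suggest_submodel_count(trial_statistics(ft$trials[1:2])),
               "at least 3")
})

test_that("build_library trains one sub-model per cluster with provenance", {
  set.seed(12)
  gains <- c(0.4, 0.9, 1.5)
  couples <- list(); profiles <- character(0)
  for (g in seq_along(gains)) for (r in 1:2) {
    u <- recovery_input(800, seed = 10 * g + r)
    gen <- hw_model(static_nl("polynomial", coefficients = c(0, gains[g], 0.2)),
                    linear_block(c(0.7, 0.3)))
    y <- simulate_hw(gen, u)$samples
    couples[[length(couples) + 1L]] <- list(
      emg = signal_trace(u, 100, kind = "normalised"),
      force = signal_trace(y, 100, kind = "normalised"),
      id = sprintf("g%d_r%d", g, r), profile = paste0("p", g))
    profiles <- c(profiles, paste0("p", g))
  }
  st <- trial_statistics(lapply(couples, `[[`, "force"), profile = profiles)
  plan <- suggest_submodel_count(st, seed = 4)
  expect_equal(plan$suggested_n, 3L)
  lib <- build_library(couples, plan, config = hw_config(nb = 2, nf = 0,
                                                         nk = 0))
  expect_equal(library_size(lib), 3L)
  refs <- vapply(lib$entries, `[[`, character(1), "training_ref")
  expect_length(unique(substr(refs, 1, 2)), 3)  # one per group
  # each sub-model reproduces its own training couple well
  for (e in lib$entries) {
    cp <- couples[[match(e$training_ref,
                         vapply(couples, `[[`, character(1), "id"))]]
    yhat <- simulate_hw(e$model, cp$emg)$samples
    expect_gte(r_squared(cp$force$samples, yhat), 0.95)
  }
})

test_that("n_override bypasses planning; single-entry library works", {
  u <- recovery_input(600, seed = 3)
  y <- simulate_hw(recovery_generator(), u)$samples
  couples <- list(list(emg = signal_trace(u, 100, kind = "normalised"),
                       force = signal_trace(y, 100, kind = "normalised"),
                       id = "only"))
  lib <- build_library(couples, n_override = 1)
  expect_equal(library_size(lib), 1L)
  expect_error(build_library(couples, n_override = 5), "out of range")
})

test_that("identification failure names the offending couple", {
  couples <- list(list(
    emg = signal_trace(rep(0.5, 400), 100, kind = "normalised"),
    force = signal_trace(runif(400), 100, kind = "normalised"),
    id = "flatline"))
  expect_error(build_library(couples, n_override = 1), "flatline")
})
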