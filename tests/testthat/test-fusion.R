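make_library <- function(models) {
  model_library(lapply(seq_along(models), function(i)
    list(id = i, model = models[[i]], training_ref = paste0("t", i))))
}

gain_model <- function(g)
  hw_model(static_nl("identity"), linear_block(g), static_nl("identity"))

test_that("run_submodels composes individual simulations", {
  lib <- make_library(list(gain_model(1), gain_model(2)))
  u <- signal_trace(c(1, 2, 3), fs = 10, kind = "normalised")
  F_ij <- run_submodels(lib, list(u, u))
  expect_equal(dim(F_ij), c(2L, 2L))
  expect_equal(F_ij[[1, 1]], simulate_hw(gain_model(1), u)$samples)
  expect_equal(F_ij[[2, 2]], c(2, 4, 6))
  # identical sub-models give identical outputs across i
  lib2 <- make_library(list(gain_model(3), gain_model(3)))
  F2 <- run_submodels(lib2, list(u))
  expect_identical(F2[[1, 1]], F2[[2, 1]])
})

test_that("residues are absolute, sign-symmetric and zero on perfect agreement", {
  F_ij <- matrix(list(c(1, 2, 3), c(2, 3, 4)), 2, 1)
  ref <- list(c(1, 2, 3))
  err <- compute_residues(F_ij, ref)
  expect_equal(err[1, 1, ], c(0, 0, 0))
  expect_equal(err[2, 1, ], c(1, 1, 1))
  err_up <- compute_residues(matrix(list(c(2, 3, 4)), 1, 1), list(c(1, 2, 3)))
  err_dn <- compute_residues(matrix(list(c(0, 1, 2)), 1, 1), list(c(1, 2, 3)))
  expect_equal(err_up, err_dn)
  expect_error(compute_residues(F_ij, NULL), "mandatory")
})

test_that("normalised residues sum to one with the 1/N tie rule", {
  expect_equal(normalize_residues(c(1, 1)), c(0.5, 0.5))
  expect_equal(normalize_residues(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(normalize_residues(c(0, 0)), c(0.5, 0.5))
  expect_error(normalize_residues(3), "N >= 2")
})

test_that("validities mirror residues and sum to N - 1", {
  mu <- compute_validities(c(0.25, 0.25, 0.5))
  expect_equal(mu, c(0.75, 0.75, 0.5))
  expect_equal(compute_validities(c(0, 1)), c(1, 0))
  set.seed(4)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    err <- normalize_residues(runif(N))
    mu <- compute_validities(err)
    expect_true(all(mu >= 0 & mu <= 1))
    expect_equal(sum(mu), N - 1)
    expect_equal(which.min(err), which.max(mu))
  }
})

test_that("fusion weight modes behave as documented", {
  mu <- c(0.75, 0.75, 0.5)
  expect_equal(fusion_weights(mu, "normalised"), c(0.375, 0.375, 0.25))
  expect_equal(fusion_weights(mu, "paper_literal"), mu)
  expect_equal(fusion_weights(mu, "switching"), c(1, 0, 0))
  # N = 2: the two averaging modes coincide because mu sums to 1
  mu2 <- compute_validities(normalize_residues(c(0.3, 0.7)))
  expect_equal(fusion_weights(mu2, "normalised"),
               fusion_weights(mu2, "paper_literal"))
  expect_error(fusion_weights(c(1.5, 0.2)), "\\[0, 1\\]")
})

test_that("paper-literal fusion with identical sub-models scales by N - 1", {
  F_star <- c(1, 2, 3)
  F_ij <- matrix(list(F_star, F_star, F_star), 3, 1)
  err <- compute_residues(F_ij, list(c(0, 0, 0)))
  mu <- compute_validities(normalize_residues(err))
  lit <- fuse_outputs(F_ij, fusion_weights(mu, "paper_literal"))
  expect_equal(lit[[1]], 2 * F_star)
  nrm <- fuse_outputs(F_ij, fusion_weights(mu, "normalised"))
  expect_equal(nrm[[1]], F_star)
})

test_that("fused output is a pointwise convex combination in normalised mode", {
  expect_equal(
    fuse_outputs(matrix(list(10, 20, 30), 3, 1),
                 array(c(0.375, 0.375, 0.25), c(3, 1, 1)))[[1]],
    18.75)
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(2:5, 1); K <- 40
    F_ij <- matrix(lapply(1:N, function(i) rnorm(K)), N, 1)
    ref <- list(rnorm(K))
    err <- compute_residues(F_ij, ref)
    w <- fusion_weights(compute_validities(normalize_residues(err)),
                        "normalised")
    fused <- fuse_outputs(F_ij, w)[[1]]
    lo <- do.call(pmin, F_ij[, 1]); hi <- do.call(pmax, F_ij[, 1])
    expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
  }
})

test_that("a zero-residue sub-model is reproduced bit-exactly (N = 2)", {
  K <- 50
  set.seed(10)
  truth <- rnorm(K)
  F_ij <- matrix(list(truth, truth + runif(K, 0.5, 1)), 2, 1)
  err <- compute_residues(F_ij, list(truth))
  w <- fusion_weights(compute_validities(normalize_residues(err)))
  fused <- fuse_outputs(F_ij, w)[[1]]
  expect_identical(fused, truth)
})

test_that("decreasing one residue never decreases that sub-model's weight", {
  set.seed(14)
  for (rep in 1:30) {
    N <- sample(2:5, 1)
    err <- runif(N, 0.1, 1)
    w1 <- fusion_weights(compute_validities(normalize_residues(err)))
    err2 <- err; err2[1] <- err2[1] * runif(1)
    w2 <- fusion_weights(compute_validities(normalize_residues(err2)))
    expect_gte(w2[1], w1[1] - 1e-12)
  }
})

test_that("relabelling sub-models permutes weights identically", {
  set.seed(15)
  err <- runif(4)
  perm <- sample(4)
  w <- fusion_weights(compute_validities(normalize_residues(err)))
  w_p <- fusion_weights(compute_validities(normalize_residues(err[perm])))
  expect_equal(w_p, w[perm])
})

test_that("mm_estimate chains the steps and honours warm-up trimming", {
  set.seed(33)
  models <- list(
    hw_model(static_nl("identity"), linear_block(c(0.5, 0.5), -0.3, nk = 1)),
    gain_model(0.8))
  lib <- make_library(models)
  u <- signal_trace(runif(200), fs = 100, kind = "normalised")
  truth <- simulate_hw(models[[1]], u)
  out <- mm_estimate(lib, list(u), list(truth))
  expect_s3_class(out, "multimodel_output")
  expect_equal(length(out$F_m[[1]]), length(u) - out$warmup)
  # the generating sub-model has zero residue, so fusion reproduces it
  keep <- (out$warmup + 1):length(u)
  expect_identical(out$F_m[[1]]$samples, truth$samples[keep])
  # weights sum to 1 at every step in normalised mode
  expect_equal(apply(out$validity$w, c(2, 3), sum),
               matrix(1, 1, length(keep)), ignore_attr = TRUE)
  expect_error(mm_estimate(lib, list(u), NULL), "mandatory")
})

test_that("two-channel estimation runs the full MIMO layout", {
  models <- list(gain_model(1), gain_model(0.5))
  lib <- make_library(models)
  u1 <- signal_trace(runif(100), fs = 50, kind = "normalised")
  u2 <- signal_trace(runif(100), fs = 50, kind = "normalised")
  ref <- list(signal_trace(u1$samples, 50, kind = "normalised"),
              signal_trace(0.5 * u2$samples, 50, kind = "normalised"))
  out <- mm_estimate(lib, list(u1, u2), ref)
  expect_length(out$F_m, 2)
  expect_equal(dim(out$validity$mu)[2], 2)
  keep <- (out$warmup + 1):length(u1)
  expect_equal(out$F_m[[1]]$samples, u1$samples[keep])      # sub-model 1 exact on ch 1
  expect_equal(out$F_m[[2]]$samples, 0.5 * u2$samples[keep])# sub-model 2 exact on ch 2
})

test_that("library serialisation round-trips and reproduces estimates", {
  models <- list(
    hw_model(static_nl("piecewise_linear", breakpoints = seq(0, 1, 0.2)),
             linear_block(c(0.4, 0.3), c(-0.2, 0.1), nk = 1)),
    gain_model(2 / 3))
  lib <- make_library(models)
  path <- withr::local_tempfile(fileext = ".json")
  library_save(lib, path)
  lib2 <- library_load(path)
  expect_equal(library_size(lib2), 2)
  u <- signal_trace(runif(80), fs = 10, kind = "normalised")
  ref <- list(simulate_hw(models[[1]], u))
  out1 <- mm_estimate(lib, list(u), ref)
  out2 <- mm_estimate(lib2, list(u), ref)
  expect_identical(out1$F_m[[1]]$samples, out2$F_m[[1]]$samples)
})
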