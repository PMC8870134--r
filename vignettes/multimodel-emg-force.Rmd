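---
title: "Estimating muscle force from surface EMG with a Hammerstein-Wiener multimodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle force from surface EMG with a Hammerstein-Wiener multimodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgforce)
```

## The estimation problem

Proportional myoelectric control needs a continuous estimate of intended
grip force from surface EMG. The EMG envelope — the low-frequency amplitude
of the rectified signal — tracks contraction intensity, but its relation to
force is nonlinear (it depends on motor-unit recruitment and fibre-type
composition) and it changes with the kind of force trajectory being
produced: a slow ramp, a staircase of static holds and a freely varying
grip exercise the muscle differently.

`emgforce` therefore avoids a single global model. It identifies a
*library* of local sub-models, one per training recording, and at each time
step fuses their outputs with time-varying weights that favour whichever
sub-model currently describes the data best.

## Sub-model structure and identification

Each sub-model is a SISO Hammerstein-Wiener (H-W) chain

$$ y(k) \;=\; h\!\big(\,G(q)\, f(u(k))\,\big), $$

a static input nonlinearity $f$, a linear dynamic block
$G(q) = B(q)/F(q)$ with input delay $n_k$, and a static output
nonlinearity $h$. Defaults: $f$ piecewise-linear with 10 uniformly spaced
breakpoints over the observed input range, $n_b = n_f = 2$, $n_k = 1$, and
$h$ the identity. The input block absorbs the envelope-to-force
nonlinearity; the linear block absorbs residual dynamics. The scale
ambiguity between $f$ and $B$ is resolved by anchoring $f(0) = 0$ with unit
mean slope.

The H-W chain is not linear in its full parameter set, so `identify_hw()`
alternates:

1. with the nonlinearity shapes frozen, the linear stage *is* linear in
   $(b, f)$ and is estimated by **recursive least squares** — innovation
   $\varepsilon(k) = y(k) - \hat\theta(k-1)^\top \varphi(k)$, adaptation
   matrix $P(k) = P(k-1) - P(k-1)\varphi\varphi^\top P(k-1) /
   (1 + \varphi^\top P(k-1) \varphi)$, update
   $\hat\theta(k) = \hat\theta(k-1) + P(k)\varphi(k)\varepsilon(k)$, no
   forgetting ($\lambda = 1$), $P_0 = 10^4 I$, $\hat\theta_0 = 0$. With
   these initial conditions the final RLS estimate equals the batch
   regularised least-squares solution with prior precision $P_0^{-1}$ —
   the test suite checks this to $10^{-8}$;
2. the nonlinearity node values, which enter linearly once $(b, f)$ are
   fixed, are refit by ordinary least squares;
3. the loop repeats (5 outer iterations by default, tolerance $10^{-6}$ on
   the packed parameter vector).

Three refinements matter in practice, all standard in system
identification:

* **Output-error regression** (`sim_regressor = TRUE`). A plain
  equation-error regression on a heavily oversampled, slowly varying
  envelope collapses onto the trivial one-step predictor — poles at the
  unit circle, a near-cancelling numerator and an arbitrary DC gain — which
  predicts one step ahead superbly and simulates poorly. From the second
  outer iteration the regressor's output lags therefore come from the
  model's *own simulated* linear-stage output (pseudolinear regression),
  which targets the free-run simulation the model is actually used for.
* **Stability projection** (`enforce_stability = TRUE`). Estimated poles on
  or outside the unit circle are reflected to $1/\bar r$; without this an
  unstable estimate diverges when cross-applied to a longer recording.
* **Best-iterate selection.** The alternating scheme is not monotone in
  simulation fit, so the returned model is the outer iterate with the
  lowest training free-run RMSE.

The convergence flag reports whether the RLS trajectory settled: relative
drift of $\hat\theta$ over the last 10% of samples below `conv_tol`
(default 5%).

## The decision unit: residues, validities, fusion

Given a library of $N$ sub-models and reference forces $F_j$ (offline
validation uses the measured force), each sub-model $i$ driven by input
channel $j$ produces $F_{ij}(k)$, and

$$ \mathrm{err}_{ij}(k) = \lvert F_{ij}(k) - F_j(k)\rvert, \qquad
   \mathrm{err}'_{ij}(k) = \frac{\mathrm{err}_{ij}(k)}
        {\sum_{i=1}^N \mathrm{err}_{ij}(k)}, \qquad
   \mu_{ij}(k) = 1 - \mathrm{err}'_{ij}(k). $$

Validities lie in $[0, 1]$, vary contrary to the residues and sum to
$N - 1$ across the library. The absolute value in the residue keeps the
normalisation meaningful (a signed residue sum could vanish or change
sign); when all residues are simultaneously below `tie_eps` ($10^{-12}$)
the tie rule assigns uniform $1/N$ shares.

Fusion weights come in three modes. The default, `normalised`, uses
$w_i = \mu_i / \sum_i \mu_i$, so the fused output
$F_{m,j}(k) = \sum_i w_{ij}(k) F_{ij}(k)$ is a pointwise convex
combination of the sub-model outputs. `paper_literal` applies the
validities directly as weights; for $N = 2$ the two coincide
($\sum \mu = 1$), but for $N > 2$ the literal form scales the output by up
to $N - 1$ (three identical sub-models would produce twice their common
output), which is why it is not the default. `switching` is
winner-take-all on the largest validity.

A structural property of this validity definition worth knowing: it
concentrates weight only mildly. Even a sub-model with zero residue
receives weight $1/(N-1)$-diluted shares when $N > 2$ (at $N = 2$ it gets
everything), so the fused estimate profits from a library whose members
are individually reasonable rather than from one excellent member among
poor ones.

## Preprocessing

Per channel, never mixed: full-wave rectification, a 6th-order Butterworth
lowpass at 1 Hz for the envelope, then min-max normalisation
$d_n = (d_r - d_{\min})/(d_{\max} - d_{\min})$. Force records go through
the same rectify-and-smooth chain. Details that matter:

* **Second-order sections.** At a cutoff-to-sampling ratio of 1/1000 a
  single transfer-function realisation of a 6th-order Butterworth is
  numerically untrustworthy (the DC gain is off by percent-level and
  forward-backward filtering collapses), so the filter is implemented as a
  cascade of bilinear-transformed biquads, each rescaled to an exactly
  unit passband reference gain. The test suite checks unit DC gain to
  $10^{-6}$ and more than 100 dB attenuation at 50 Hz against the analytic
  magnitude response $\lvert H \rvert = (1 + (f/f_c)^{2n})^{-1/2}$.
* **Zero-phase by default.** Offline estimation filters forward and
  backward (no group delay, squared magnitude response) with odd-reflection
  padding and steady-state initial conditions; a causal single-pass mode
  exists for online use and inherits the usual transient and lag.
* **Frozen normalisation.** Min-max parameters are fitted on training data
  only and reused on validation data; out-of-range normalised values are
  passed through unclipped so the mapping stays invertible. The degenerate
  constant-trace case is an error, not a silent division by zero.
* **Envelope-domain decimation.** After the 1 Hz envelope filter the
  signals carry no content near the original 500 Hz Nyquist, so scenario
  runs decimate by 10 (to 100 Hz) before identification and estimation.
  This is a modelling-rate choice, not a data reduction: it shortens the
  RLS passes and, equally important, moves the sampling rate closer to the
  signal bandwidth, which improves the conditioning of the lagged
  regression.

## Choosing the number of sub-models

The library size is driven by the data: each preprocessed trial is reduced
to a feature row (quartiles, IQR, variance, skewness, kurtosis of its
envelope), features are standardised, and k-means with a fixed seed and 10
restarts is scored by the mean silhouette width for each candidate $N$;
the best-scoring candidate is suggested. All-alike trials make the
silhouette undefined and fall back to $N = 1$. A manual override always
wins. One sub-model is then trained per cluster, on the trial nearest the
cluster centroid.

## The ANN baseline

The comparison model is a one-hidden-layer perceptron: 7 tangent-sigmoid
hidden units, 4 output neurons, linear output layer, trained in full batch
by Levenberg-Marquardt on the analytic residual Jacobian
($ (J^\top J + \lambda I)\,\delta = -J^\top r$, damping multiplied by 10 on
rejected steps and divided by 10 on accepted ones, so the recorded loss
history is non-increasing). Inputs are the three preprocessed envelopes
plus two lagged samples each (9 features); the force channel is trained
against output 1 and the unused outputs against zero targets, keeping the
4-output architecture intact while reporting only the force estimates.

## The synthetic testbed

The generator emulates a grip-force experiment: five force profiles —
`step` (five 10 N increments, 10 s each), `saw` (two back-to-back ramps to
50 N), `vol` (a seeded smoothed random walk in $[0, 50]$ N — "freely
varying" made reproducible), `single_level` (steady 50 N) and `circle`
(one half-cosine rise and fall over 10 s) — at 1000 Hz, four trials per
profile, three EMG channels. EMG is band-limited noise (20-500 Hz)
amplitude-modulated by $g \,(F/F_{\max})^{\gamma}$ with per-channel gains
$(1.0, 0.8, 1.2)$ and exponents $\gamma = (0.8, 1.0, 1.3)$, embedding the
nonlinearity (and optionally a first-order hysteresis) that motivates the
H-W structure. The recorded force carries Gaussian measurement noise of
0.2 N, consistent with the accuracy class of a handgrip dynamometer; it
also keeps the steady profile from having a degenerate min-max range.
Everything is seeded per trial and regenerates bit-identically.

What the generator does *not* emulate: motor-unit recruitment and firing
statistics, electrode crosstalk, movement artefacts, fatigue, or
inter-subject variability. Passing tests on this testbed demonstrate that
the estimator chain is implemented correctly and behaves as designed on
data with a known, plausibly EMG-like structure — they do not certify
accuracy on physiological recordings.

## Validation scenarios

* **Scenario 1** — same-profile generalisation: three sub-models trained on
  three step trials, tested on the held-out fourth.
* **Scenario 2** — two known profiles (step, circle) estimate an arbitrary
  target (vol).
* **Scenario 3** — three known profiles (step, circle, saw) against the
  same target.

Held-out trials never enter any sub-model's training data, and
normalisation is frozen on the training side. Metrics are the coefficient
of determination $R^2 = 1 - SS_{res}/SS_{tot}$ (computed on normalised
signals; can be negative) and RMSE in normalised units. Computation time
is logged but never asserted — it measures hardware, not the method.

On this testbed (seeds 1-10, defaults throughout) the multimodel reaches a
mean scenario-1 $R^2$ of about 0.97 and scenario-3 about 0.97 as well but
consistently no higher than scenario 1 — cross-profile libraries do not
beat same-profile ones on average, and adding a third known profile does
not automatically help. The test suite asserts exactly the quantities this
vignette states: the scenario-1 fused fit (and that fusion is not worse
than the best individual sub-model by more than 0.02 $R^2$), and the
scenario-3-vs-1 ordering over ten seeds; the acceptance script recomputes
the per-scenario tables from scratch.

## Numerical choices and degenerate inputs

* RLS: $P$ re-symmetrised after every update; non-finite inputs rejected;
  a zero regressor leaves the state untouched.
* Nonlinearity refits: ridge $10^{-9}$ on the normal equations (hat-basis
  columns for unvisited piecewise segments are all-zero); piecewise-linear
  output blocks are isotonic-projected before inversion.
* Piecewise-linear evaluation extrapolates linearly from the end segments
  rather than clamping, so validation data slightly outside the training
  range stay informative.
* Warm-up: the first $\max(n_b + n_k, n_f)$ samples of a simulation are
  excluded from residues and metrics (zero initial conditions).
* Degenerate inputs error early and loudly: constant traces in
  `minmax_fit()` and `identify_hw()`, single-sample traces in the filter,
  missing references in the decision unit.
* Problem sizes in the tests are the generator's trial durations (50 s
  profiles, 10 s circle) at the documented rates; the acceptance script
  uses the same.

## Known limitations

* The decision unit needs a reference force at estimation time, which
  exists offline but not in a deployed prosthesis; how to obtain validities
  reference-free is an open design question outside this package's scope.
* Sub-models are SISO; multichannel estimation drives each sub-model with
  each input channel rather than fitting true MISO models.
* The validity scheme's weight dilution for $N > 2$ (above) bounds how much
  fusion can outperform a uniformly good library.
* The ANN baseline deliberately mirrors a fixed architecture (7 hidden
  units, LM, no early stopping or regularisation); it is a comparison
  point, not a tuned competitor.
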