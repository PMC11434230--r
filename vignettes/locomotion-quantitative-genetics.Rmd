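---
title: "Quantitative genetics of locomotion behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of locomotion behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormqg)
```

`wormqg` analyses the evolution of nematode locomotion behavior in
experimental populations: how the genetic covariance structure of
behavioral traits diverges under drift while the traits themselves stay
put. This vignette documents the models, the tunable parameters, the
synthetic-data generators, and the numerical and design choices, in the
order the pipeline runs them.

## 1. The behavioral model

Movement is a three-state continuous-time Markov chain over still (`S`),
forward (`F`) and backward (`B`). The generator `Q` has non-negative
off-diagonal rates `q_ij` (per second) and zero row sums; the six non-self
rates in the fixed order `SF, SB, FS, FB, BS, BF` are the component traits
of locomotion, log-transformed when they act as phenotypes. Mean dwell time
in state `i` is `1/q_i` with `q_i = -Q[i,i]`; transition probabilities over
a lag are `P(Δt) = exp(Δt·Q)`; long-run state frequencies `f` solve
`fQ = 0`.

The Markov assumption is deliberately a useful approximation: real worms
have non-exponential dwell times. The package ships a diagnostic
(`predicted_state_frequencies()`) comparing observed time-in-state
fractions against the fitted stationary distribution; for Markov data the
points sit on the identity line, and the test suite demonstrates that
gamma-distributed dwell times produce a detectable systematic deviation.

### Estimation

Tracks are compressed losslessly to counts `n(i, j, Δt)`
(`compress_tracks()`); because the compressed likelihood is algebraically
identical to the per-pair sum, the suite checks equality to 1e-10. Lags
within `dt_tolerance` (default 1e-6 s) are merged onto their
count-weighted mean; distinct lags arise naturally from dropped frames.

Rates are estimated under independent log-normal priors
`ln q ~ N(ln 2, 0.6²)` — a weakly informative prior centered on a 2/s
rate, the scale of worm behavioral transitions. The default estimator is
the posterior mode (BFGS on the log scale) with a Laplace approximation
supplying posterior draws; `method = "mcmc"` runs an adaptive random-walk
Metropolis chain seeded at the mode with the Laplace covariance as
proposal. Both must (and do) pass the same recovery tests. The matrix
exponential is computed from one eigendecomposition of `Q` reused across
all lags, with a `Matrix::expm` fallback for numerically defective
generators, and is contract-tested against a truncated Taylor series.

If a movement state is never observed, its exit rates are not identified:
the posterior is prior-dominated and — a subtler effect — the joint mode
can drift to large exit rates that mimic "invisible" visits to the unseen
state. `fit_transition_rates()` therefore flags exit rates from unobserved
states explicitly rather than trusting the posterior-width heuristic alone.

## 2. Broad-sense G-matrices from inbred lines

For a panel of inbred lines scored in technical-replicate blocks, the
multivariate mixed model is

    y = μ + T*H*D + L + B + e

with the six log rates as a joint response, standardized temperature,
humidity and density (all interactions) as fixed effects — plus a
two-level `year_flag` when the panel spans assay years — and unstructured
6×6 covariances for line (`L`), block (`B`) and residual. The genetic
covariance matrix is **half** the line covariance, the broad-sense
convention for fully inbred lines (between-line variance is twice the
additive variance of the base population).

The reference fit is a conjugate Gibbs sampler written for this model:
matrix-normal updates for fixed and random effects, inverse-Wishart
updates for the covariances. Priors are `IW(ν = 7, S₀)` with `S₀` half
the diagonal phenotypic-variance matrix — minimally informative, scaled to
the data. Desk-scale defaults (6,000 iterations, 1,000 burn-in, thinning
10) keep a fit to a 150-line panel in seconds; publication-scale settings
are plain arguments. Convergence is monitored on the trace of G: the fit
is flagged unless the lag-1 autocorrelation of retained draws is below
0.05 (allowing for the ~1/√draws noise floor of the autocorrelation
estimate itself) and the effective sample size exceeds 50.

A moment estimator (`method = "moments"`: between-line covariance of
covariate- and block-adjusted line means, minus within-line covariance
scaled by replication) provides a fast point estimate. It backs the two
resampling nulls — label permutation (`permutation_null_gmatrices()`,
shuffling line and block identities independently) and line subsampling
(`subsample_refit()`, e.g. 60 of 188 lines) — because those nulls consume
only point estimates, and it agrees with the Gibbs posterior mean within
tolerance on synthetic data (tested).

**What recovery can and cannot show.** A 6×6 covariance estimated from
`n` lines has an irreducible relative Frobenius error of about `√(2/n)`
(~12% at 150 lines) from finite-line sampling alone, before any
measurement noise. Recovery tests at that scale therefore run close to
their tolerance by construction; the consistency of the estimator is
checked separately on a ladder of panel sizes.

## 3. Comparing G-matrices

* **Size**: the trace, computed per posterior draw.
* **Shape**: eigendecomposition; `gmax` is the first eigenvector.
  Eigenvector signs are fixed (largest-magnitude loading positive) for
  reproducible reports.
* **Angles**: `Θ = acos(g_i·g_j / |g_i||g_j|)` in degrees, folded to
  [0°, 90°] because `g` and `-g` span the same axis. Numerically the
  package uses the chord form `2·asin(min(‖u−w‖, ‖u+w‖)/2)`, stable where
  `acos` loses precision near parallel vectors. The no-alignment null is
  the angle between pairs of vectors with i.i.d. Uniform(−1, 1)
  coordinates (1,000 pairs by default).
* **Eigentensors**: each population's G is half-vectorized with √2-scaled
  off-diagonals, making Euclidean geometry on the 21-vectors equal
  Frobenius geometry on the matrices (tested as an exact isometry).
  Matrices are centered across the m populations and their covariance
  (denominator m − 1, treating populations as a sample) accumulated per
  posterior draw, pairing draws across populations by index; the
  posterior-averaged 21×21 tensor is eigendecomposed into orthonormal
  eigentensors `E_i` with eigenvalues `α_i`, and each `E_i` into
  trait-space eigenvectors `e_ij`. At most m − 1 eigenvalues are nonzero
  (asserted exactly in the tests).
* **Two distinct nulls, never interchanged**: the uniform-vector null is
  for angles ("no alignment"); the finite-line sampling null
  (`tensor_sampling_null()`) is for `α_i` ("no divergence beyond
  sampling"), built by re-estimating every population's G from a finite
  number of lines drawn from one pooled matrix. The pooled matrix is the
  mean of the population means (re-sampling from each population's own
  posterior is a flagged alternative the package does not default to).

## 4. The selection surface

Relative fitness is `w = exp(log-fertility)/mean(exp(log-fertility))`, so
mean fitness is exactly 1. The quadratic surface is estimated by partial
regression

    w = α + ½ Σ γ_kk z_k² + Σ_{k1<k2} γ_k1k2 z_k1 z_k2 + ε

with the ½ built into the diagonal design columns, so coefficients are the
quadratic gradients γ directly — no post-hoc doubling, the classic
pitfall. Traits are centered; variance standardization is off by default
(the traits stay on the log-rate scale). Linear gradients are excluded by
default — after adaptation, directional selection is not expected — and
can be added with a flag. Posterior draws come from the conjugate
normal–inverse-χ² posterior under a flat prior, so the posterior mode is
the least-squares fit. Residual normality is reported (Shapiro–Wilk).

Canonical analysis `Λ = U'γU` sorts eigenvalues descending: positive =
disruptive, negative = stabilizing. The null for the rotated eigenvalues
permutes fitness across lines, refits γ, and rotates by the **fixed**
observed `U`. Alignment between divergence directions (`e_ij`) and
canonical axes uses Pearson correlations of the loadings, recomputing `U`
for each γ posterior draw to propagate uncertainty.

## 5. Drift expectations

Under the infinitesimal model, genetic variance decays as
`V(t) = V₀(1 − 1/(2Nₑ))^t`. The individual-based oracle
(`simulate_drift_panel()`) tracks Nₑ diploid parents: offspring breeding
values are midparent plus a segregation deviation with covariance half the
*current* realized G — the standard recursion whose expectation reproduces
the geometric decay (verified against the closed form over 200 replicates
in the acceptance tests). Realized trajectories fluctuate around the
expectation by ~√(2/Nₑ) per generation, compounding as a random walk —
single trajectories are noisy by nature, which is exactly the point of the
comparison.

`drift_envelope_compare()` rotates each generation's G posterior into the
canonical frame, anchors the decay curve at the ancestral posterior mode
(mean available as an option) per axis, and flags axes whose evolved 95%
intervals exclude the drift expectation. Decay is applied independently
per canonical axis, matching per-axis reference curves; uniform
whole-matrix shrinkage is equivalent when G shrinks proportionally
(tested as an identity).

## 6. Synthetic data: what it emulates, what it does not

The simulators generate every input with known truth:

* `simulate_tracks()`: exact Gillespie paths (exponential holding times,
  jump probabilities `q_ij/q_i`), observed on a 4 Hz frame grid inside a
  20-minute movie, with the first 300 s discarded (plate handling
  perturbs the worms) and i.i.d. frame drops producing mixed lags. Track
  durations are exponential with mean 60 s (the scale of real tracker
  segments); a fixed-duration option serves recovery studies. Initial
  states come from the stationary distribution, removing transient bias.
* `simulate_line_phenotypes()`: line effects from `MVN(0, 2G)` (so half
  the between-line covariance is G), block effects, block-level
  standardized covariates with configurable effects, and replicate
  residuals. Defaults — 150 lines, 3 blocks per line, ~20 lines per
  block, residual diag(0.5), block sd 0.1 — mirror a realistic panel
  (blocks of 2–22 samples, each line in ≥ 2 blocks).
* `simulate_fitness()`: evaluates the quadratic surface exactly plus
  Gaussian noise.
* `simulate_drift_panel()`: the drift oracle above, at Nₑ = 10³ in the
  pipeline (the effective size of the experimental populations).

Not emulated: video imaging, worm collisions and track fragmentation
biases, male/hermaphrodite mixtures (simulations are single-sex; sex
separation belongs upstream of this package), density-dependent behavior,
and non-Markov dwell structure (except where planted deliberately to test
the diagnostic). Passing recovery tests on these simulations shows the
estimators are correct under the model's assumptions — not that real
tracker data satisfy those assumptions; the state-frequency diagnostic
exists precisely to probe that on real data.

## 7. Numerical choices and degenerate inputs

* Trait order `(SF, SB, FS, FB, BS, BF)` is enforced at every interface.
* `P(dt)` entries are clamped to [0, 1] only within 1e-12; a positive
  transition count where the model puts zero probability yields −∞, not
  an error.
* Reducible generators: a unique-but-boundary stationary distribution
  warns; a non-unique one errors.
* Asymmetric matrices are symmetrized within 1e-9 and rejected beyond.
* Aliased fixed-effect columns (few blocks, full interaction design) are
  dropped automatically.
* Lines with a single replicate are dropped with a warning; fewer than 10
  lines warns; a single block errors (block variance inestimable).
* Eigenvector sign: largest-magnitude loading positive. Posterior modes
  are kernel-density modes; 83%/95% intervals are equal-tailed quantile
  intervals (83% non-overlap is the two-posterior comparison convention).
* All simulators and fits are bit-reproducible given (seed, config); the
  pipeline writes a manifest of seeds and file checksums, and reruns are
  byte-identical.

## 8. Problem sizes

Tests and the acceptance script run at desk scale, chosen so the full
suite completes in minutes while keeping each check well-powered: 100–2,000
tracks for rate estimation; panels of 40–150 lines with Gibbs runs of
600–15,000 iterations; 20–300 permutations for nulls; 100–200 replicates
for drift Monte-Carlo comparisons. Publication-scale settings (e.g.
2.1M MCMC iterations, 1,000 permutations) are reachable through the same
arguments.

## Known limitations

* The G-matrix sampler assumes crossed line/block random effects with a
  shared residual; pedigree/marker-based relatedness (an A-matrix random
  effect) is out of scope.
* The Laplace default for transition rates understates posterior skew for
  very sparse states; use `method = "mcmc"` there (the unobserved-state
  flag tells you when).
* Fitness estimation itself (fertility assays to BLUPs) is upstream;
  `prepare_relative_fitness()` expects log-scale, covariate-adjusted
  values.
* The permutation null for G refits by the moment estimator by default;
  full Gibbs refits per permutation are available but slow.
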