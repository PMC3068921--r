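---
title: "Estimating priors over visuomotor transformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating priors over visuomotor transformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmprior)
```

## The problem

When a reaching movement is made under a novel visuomotor transformation —
a mapping between where the hand actually is and where it is displayed —
a single trial of terminal feedback is not enough to identify the mapping.
A 2x2 linear transformation `T` has four parameters `(a, b, c, d)` with
`v = T h` (cursor `v`, hand `h`, both relative to the start of the reach),
but one trial supplies only two equations. The reach on the *second* trial
of a batch therefore reveals how the mover resolves the ambiguity: it
reflects the combination of the first trial's evidence with a *prior* over
transformations. `vmprior` implements the machinery for turning
second-trial reaches into an estimate of the full 4x4 covariance structure
of that prior, together with the synthetic experiment used to validate the
estimator by parameter recovery.

## The observer model

The observer's belief over `t = vec(T) = (a, b, c, d)` is multivariate
Gaussian with mean at the identity transformation (hands are normally seen
where they are) and covariance `Sigma_0`, the quantity being estimated.
Writing the cursor observation as a linear function of `t` through the
design matrix

```
A(h) = | h_x  h_y  0    0   |
       | 0    0    h_x  h_y |
```

with isotropic Gaussian cursor noise of variance `sigma_v^2`, the belief
update after observing `(h, v)` is the standard Gaussian linear-model
(conjugate) update of the precision `Lambda` and mean `mu`:

```
Lambda' = Lambda + A(h)' A(h) / sigma_v^2
mu'     = Lambda'^{-1} (Lambda mu + A(h)' v / sigma_v^2)
```

The hand is treated as noiseless; all observation noise is carried by the
displayed cursor. On each trial the observer takes the MAP transformation
(the posterior mean) and aims so that the predicted cursor lands on the
target: the predicted hand is `T_MAP^{-1} x*`. The exact form of the
update is checked in the test suite against a brute-force discretized
posterior on a 21^4 grid.

Only the ratio `Sigma_0 / sigma_v^2` is identified — scaling both leaves
every prediction unchanged — so `sigma_v^2` is fixed at 1 cm^2 and all
statements about the prior concern its *shape* (correlations and
covariance-ellipse orientations), not its absolute size. To make this
invariance hold exactly in floating point, the small jitter applied to the
belief precision at initialization is proportional (`1e-6` times the mean
diagonal of the precision) rather than absolute.

Four rival observers share the same Bayesian skeleton but assume different
transformation families: a **shift** (`v = h + s`, 2 parameters), a
**rotation and uniform scaling** (polar coordinates about the start,
parameters `(dtheta, g)`), an **affine** map (`v = T h + s`, 6 parameters,
block-diagonal prior between linear and shift parts, 13 free covariance
parameters), and a **no-adaptation** observer that always aims at the
target. The rotation-scaling observer's polar noise (radial variance 1
cm^2, angular variance 0.01 rad^2) is chosen to be isotropic at 10 cm
eccentricity, the middle of the target region: with targets at 6-16 cm,
`r^2 * sigma_theta^2 = 1 cm^2` forces `sigma_theta^2 = 0.01 rad^2`.

## Fitting the prior

For each transformed batch, the model predicts the second-trial hand from
the first trial's evidence alone (later trials follow different statistics
across sessions and are never used for estimation). The fit minimizes the
saturating robust cost

```
C = sum_i min(e_i, c),    c = 10 cm
```

over per-batch Euclidean prediction errors `e_i`; the saturation bounds
the influence of outliers while keeping full sensitivity in the 4-10 cm
range where model errors typically live. `c` is configurable
(`robust_cost_spec()`), and model comparison instead averages errors
capped at 20 cm.

The optimization variable is the upper-triangular factor `U` of the
precision, `Lambda = U'U + 1e-6 I`, with the diagonal of `U` bounded below
at `1e-6`; this guarantees a symmetric positive-definite fitted covariance
without constraints on the covariance itself. The optimizer is
bound-constrained L-BFGS-B with numerical gradients; 100 random restarts
(default; reduced in scaled-down studies) are drawn as `Lambda_0 = B'B +
1e-6 I` with `B` iid Gaussian (`prior_init_sd = 1`), and the lowest-cost
restart wins, ties broken by restart order. The cost surface has
near-flat directions — in particular the overall scale of a nearly
unconstrained prior — so the *covariance matrix itself* is not a stable
summary of a fit; the pairwise correlations and ellipse orientations that
all downstream statistics use are stable, which is exactly why the
validation study scores recovery on those quantities.

## The synthetic experiment

`simulate_session()` generates the observable structure of a session: for
each transformation batch, a transformation is drawn, the first reach is
placed at the target centre (the washout assumption: interleaved veridical
batches return behaviour to baseline, and observed first reaches cluster
tightly around the target), cursors are `T h` plus isotropic 1 cm Gaussian
noise — the single noise channel of the model — and reaches from trial 2
on are produced by a model observer carrying a known generating prior.
Batches end on a target hit (cursor within 3 cm) after at least 3 trials,
spontaneously with probability 0.2 after each trial from the 8th on, or at
a hard cap of 30 trials (a simulation safeguard only).

Two transformation distributions are provided. The **correlated**
distribution draws `a, d ~ Uniform(lo, hi)` and a shared off-diagonal
element `b = c ~ N(0, sigma_bc^2)`, giving a perfect +1 correlation
between off-diagonal elements and a +45 degree covariance orientation.
The **uncorrelated** distribution (used to probe a prior without teaching
new correlations) draws `a ~ N(1, sigma^2)` and `c ~ N(0, sigma^2)` and
solves `b`, `d` so the transformation is exactly consistent with the
first trial's evidence; one element per row is free, which is the only
self-consistent reading of the construction. Every draw is rejected and
resampled unless (i) the image of the whole target rectangle stays within
the central 80% of the screen and (ii) no target would require a hand more
than 30 cm from the start circle; both rules are evaluated on rectangle
corners, which is exact for linear maps.

### Calibration of the workspace constants

The reach limit (30 cm), the 80% screen rule, the 11 cm target-rectangle
offset and the batch termination rules are stated facts of the paradigm.
The uniform range of `a`/`d`, the off-diagonal SD, the uncorrelated draw
SD, the rectangle size and the screen geometry are not; they are
configuration with defaults calibrated *jointly* so that (a) the
post-rejection moments of the correlated distribution land near the
published per-element means `(1.17, 0.03, 0.03, 0.99)` and SDs
`(0.53, 0.54, 0.54, 0.41)`, and (b) the uncorrelated mode's pairwise
correlations stay small (published maximum 0.13). The joint constraint
matters: rejection by the reach rule couples the drawn and solved diagonal
elements (`a` and `d`), and workspaces calibrated against (a) alone can
leave an `a`-`d` correlation in the uncorrelated mode well outside the
published range. The calibrated
defaults are `a, d ~ U(0.1, 1.9)`, `sigma_bc = 0.6`,
`sigma_ac_uncorr = 0.55`, a 20x10 cm target rectangle centred 11 cm ahead,
and a 140x55 cm screen centred 4 cm ahead of the start circle; the test
suite asserts both calibrations (moments within 0.15 of the published
row at n = 10,000; all uncorrelated correlations below 0.2 at n = 1130). A small fraction of simulated first-trial
evidence admits no consistent uncorrelated transformation at all under the
rejection rules; since the experiment only ever presented evidence with an
eligible swap, the simulator redraws such evidence.

### What the generator does not emulate

Motor noise on the hand itself (first reaches are exactly at the target;
the model's single noise channel is the cursor), within-session drift of
the prior, the full-feedback trials of later sessions, and veridical
batches (which carry no information for fitting) are not simulated.
Passing recovery tests therefore demonstrate that the estimator works
under the model's own assumptions at realistic noise, not that those
assumptions hold for human data.

## Statistics on fitted priors

For each of the six element pairs, `cov_to_pair_stats()` reports the
correlation `r_jk` and the orientation `theta_jk` of the long axis of the
marginal covariance ellipse, `theta = 0.5 atan2(2 S_jk, S_jj - S_kk)`,
on the axial range (-90, 90] (an axis is defined modulo 180 degrees). An
exactly isotropic marginal has no defined axis; it is reported as 0
degrees with a degeneracy flag so that resampling pipelines remain
deterministic. Axial means double the angles, average on the circle, and
halve. Bootstrap confidence limits on an orientation resample batches with
replacement and refit, warm-starting each refit at the full-data optimum
plus random restarts; the 95% interval is the central interval on the
doubled-angle circle. A calibration caveat: because the fitter conditions
on *recorded* evidence while responses were generated from the displayed
evidence, the orientation estimate carries a small systematic tilt that
does not shrink with session length. For moderately coupled priors the
bootstrap interval is wide relative to this bias and empirical coverage
sits at its nominal 95% (the test suite verifies this on simulated
sessions); for very strong couplings the interval narrows until the bias
dominates and coverage falls below nominal. Confidence limits on very
sharp orientations should therefore be read as slightly optimistic. Across-subject consistency of correlations is
tested with a one-sample t-test against zero and an exact one-sample
Kolmogorov-Smirnov test against Uniform(-1, 1); a zero-variance sample
(every subject identical) is handled as a limiting case rather than an
error.

## The validation study

`run_validation_study()` is the package's own acceptance surface: sample a
random generating prior as `(B'B + 1e-6 I)^{-1}` with `B` iid Gaussian,
simulate a session of 150 transformation batches, refit by the robust
multi-restart procedure, and score the median absolute difference in
pairwise correlation, the fraction of sign disagreements, and the axial
angle error, aggregated over the six pairs — against the chance floor
from independent random prior pairs (`random_prior_baseline()`: median
absolute correlation difference about 0.72, sign disagreement 50%). The
default configuration is the full published scale (825 datasets,
best-of-100 fits); the bundled acceptance script and the test suite run
30-60 datasets with best-of-20 fits, which keeps the complete study inside a
few minutes of a single CPU while leaving the per-dataset conditions
(150 batches, 1 cm noise) untouched: the recovery error is dominated by
per-dataset sampling noise and the restart budget, not by the number of
datasets, so the reduced study estimates the same quantity with a wider
Monte-Carlo error.

A note on the model-free adaptation analysis: the regression of the
adaptation ratio on the angular separation of successive targets is flat
for observers that generalize globally (a shift observer's ratio is
exactly constant). The standard linear-map observer itself predicts a
*weak* angular decay — one trial's evidence constrains the map mostly
along the probed direction — so simulated standard-observer data can show
a small negative slope; the test of the flat-slope property uses shift
observer data for that reason.

## Numerical choices and limitations

* Determinant floor `1e-10` for all matrix inversions; near-singular
  transformations are rejected by the generator and produce a saturated
  error (not a crash) inside the fitting objective.
* Optimizer tolerances: `factr = 1e7` (about 1e-9 relative), `maxit =
  200`; bootstrap refits use looser settings since they start at the
  full-data optimum.
* The fitting objective is evaluated in compiled code (RcppArmadillo);
  the R-level observer implementation is the reference, and the two are
  held together by an equivalence test.
* Ten-fold cross-validation assigns batch `i` to group `((i - 1) mod 10)
  + 1`, the evenly-spaced scheme that keeps folds balanced over the
  session.
* Problem sizes in the test suite (sessions of 12-200 batches, 100
  bootstrap resamples, 100 coverage sessions, 30 recovery datasets) were
  chosen as the smallest scales at which the checked properties are
  stable; all scale parameters are function arguments.
* Sessions are fit as static priors; learning of the prior across
  sessions is expressed only by fitting sessions separately, and
  hierarchical observers that infer transformation *structures* are out
  of scope.
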