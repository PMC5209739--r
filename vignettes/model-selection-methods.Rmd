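---
title: "Thermal performance curves for seagrass photosynthesis: models, fitting and dual-criterion selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal performance curves for seagrass photosynthesis: models, fitting and dual-criterion selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcselect)
```

## The problem

Gross photosynthesis of aquatic plants rises gradually with temperature to a
thermal optimum and then declines steeply toward an upper thermal limit.
Many empirical equations describe this unimodal, negatively skewed shape
equally well, so choosing among them by fit statistics alone is weakly
informative.  What distinguishes candidate equations in practice is whether
their parameters are *biologically meaningful* — stable, physically
interpretable, and transferable to other analyses.  For a
photosynthesis–temperature curve the meaningful quantities are the maximum
rate `P_max`, the thermal optimum `T_opt` at which it is attained, the upper
limit `T_max` at which the rate reaches zero, and the sub-optimal
temperature sensitivity `Q10`.

`tpcselect` implements a selection procedure that weighs goodness of fit and
the ease of obtaining these parameters *jointly*: twelve published
temperature-response models are fitted to every treatment (one
species × season × location dataset), compared with four statistics, and a
best model is chosen as the intersection of a goodness-of-fit set and a
meaningful-parameter set.

## The twelve models and their reparameterisation

All twelve registry models (`tpc_registry()`) satisfy four structural
criteria: unimodal rise-and-fall shape; asymmetry about the optimum
(`P(T_opt - dT) != P(T_opt + dT)` is attainable); at most 4 free parameters;
and an unambiguous formulation in terms of `P_max` and `T_opt`.  The last
criterion required re-deriving each published equation so that
`P(T_opt) = P_max` holds *by construction*.  The general recipe: write the
published curve `g(T; shape)`, impose stationarity `g'(T_opt) = 0` to
eliminate one internal parameter in favour of `T_opt`, and normalise
`P(T) = P_max * g(T)/g(T_opt)`.  The package evaluates each model in this
normalised form, which makes the optimum identity exact to machine
precision rather than approximate.

Details worth recording (each can be re-derived in a few lines):

* **Briere-1** `P = a T (T - T_min) sqrt(T_max - T)`: stationarity at
  `T_opt` forces `T_min = T_opt (4 T_max - 5 T_opt) / (2 T_max - 3 T_opt)`,
  so the model is written purely in `(P_max, T_opt, T_max)` and `T_min` is
  a derived algebraic quantity.  Validity requires
  `T_opt < T_max < 1.5 T_opt` (°C); outside this region the derived `T_min`
  would exceed `T_opt`.  **Briere-2** generalises the square root to
  exponent `1/m` and obeys the analogous condition
  `T_max < (1 + 1/m) T_opt`.
* **Deutsch**: Gaussian of half-width `a` below the optimum, inverted
  quadratic above, zero at `T_max`; lower limit `-Inf`.
* **Johnson**: the enzyme-kinetics (high-temperature inactivation) form on
  the absolute temperature scale, with activation and inactivation energies
  `e < e_h` (eV) and `T_opt` as an explicit parameter.  The rate tends to
  zero at 0 K and declines only asymptotically above the optimum, so
  `T_max = +Inf`.
* **Lactin** (lambda-augmented, 4 parameters):
  `P = exp(rho T) - exp(rho Tm - (Tm - T)/delta) + lambda`.  Both `Tm` and
  `lambda` are eliminated using stationarity and `P(T_opt) = P_max`, leaving
  `(P_max, T_opt, rho, delta)` with the joint constraint `rho * delta < 1`
  (otherwise the stationary point is a minimum).  Whether a finite low-
  temperature zero crossing exists depends on the sign of the resulting
  offset, hence `T_min` is *undefined or finite*; the upper crossing is
  transcendental and found numerically.
* **O'Neill**: `((T_max - T)/(T_max - T_opt))^x exp(x (T - T_opt)/(T_max -
  T_opt))` with shape exponent `x`; `T_max` is nominally a parameter, but
  the curve approaches zero so flatly near `T_max` that the estimate is
  often poorly constrained — the model is therefore *not* counted in the
  meaningful-parameter set.
* **Ratkowsky** (squared square-root-type):
  `P = [b (T - T_min)(1 - e^{c (T - Tm)})]^2`; stationarity fixes
  `Tm = T_opt + log(1 + c (T_opt - T_min))/c`.  The square makes the curve
  nonnegative everywhere, so the upper zero is located by root finding on
  the signed pre-square curve.
* **Room**: split Gaussian with independent widths below and above the
  optimum (asymmetry comes from `sigma_low != sigma_high`); both thermal
  limits are infinite.
* **Spain**: exponential rise times exponential cutoff
  `A e^{rho T}(1 - e^{c (T - TL)})`; `TL` eliminated by stationarity;
  lower limit `-Inf`, upper zero found numerically.
* **Thebault**: linear rise from a finite `T_min` times exponential decay,
  `P_max ((T - T_min)/(T_opt - T_min)) e^{-(T - T_opt)/(T_opt - T_min)}`;
  declines asymptotically, so `T_max = +Inf`.
* **van der Heide**: cubic with a repeated lower root,
  `P = A (T - T_min)^2 (T_max - T)`.  Stationarity forces
  `T_min = 3 T_opt - 2 T_max`: the three cardinal temperatures are mutually
  interdependent, which restricts the shapes the model can take and is the
  structural reason for its weak performance on negatively skewed curves.
* **Yan and Hunt** (3 parameters):
  `P = P_max ((T_max - T)/(T_max - T_opt)) (T/T_opt)^{T_opt/(T_max - T_opt)}`
  on `0 <= T <= T_max`, zero otherwise.  It assumes `T_min = 0` °C, and is
  written *only* in terms of `P_max`, `T_opt`, `T_max`.  A four-parameter
  variant with a free `T_min` exists; it is deliberately not implemented
  because it needs data over a wider temperature range than the 7-level
  design emulated here (the registry and fitting layer would accept such an
  extension without structural change).

Where a model's original publication admits several algebraic routes to the
`(P_max, T_opt)` form, the choice made here is the one that satisfies every
capability flag in the registry (finite vs infinite limits, closed-form vs
root-found `T_max`) and keeps the parameter count at 3–4.

### Supports and clamping

Evaluation returns the raw model value inside each model's support and 0
outside it (e.g. beyond `T_max` for finite-limit models, below 0 °C for Yan
and Hunt); negative raw values inside the support (possible for the cubic
and bracket-type forms at the edges) are clamped to zero.  Root finding for
transcendental upper limits uses the *unclamped* signed curve, brackets the
crossing on `(T_opt, T_opt + 60]`, and polishes it to 1e-6 °C; a crossing
that cannot be bracketed in that window is reported as an `"unsatisfactory"`
status with `NA`, never as an error, since a fitted curve without a usable
upper limit is a scientifically meaningful outcome.

## Fitting

Fitting is plain (unweighted) least squares on replicate-level
observations, matching the design `n = 42` (7 temperatures × 6 replicates).
The optimiser is Levenberg–Marquardt (`minpack.lm::nls.lm`) with box
bounds — `P_max` in `(0, 10 × max rate]`, `T_opt` within the observed range
± 5 °C, finite `T_max` up to 60 °C beyond the warmest observation — chosen
to contain every plausible seagrass parameterisation while preventing
runaway extrapolation.  Joint constraints that a box cannot express
(`t_opt < t_max`, the Briere validity conditions, `rho * delta < 1`) are
handled by penalising invalid parameter vectors with large residuals, which
makes the multistart robust to fractional-power domain errors without
raising.

Starting values form a deterministic grid: `P_max` at the observed maximum
rate and 1.2 × it; `T_opt` at the temperature of the maximum and ± 3 °C;
`T_max` (where present) at 1, 5 and 15 °C above the warmest observation;
shape parameters at fixed registry defaults.  Every model gets at least six
valid starts and the best converged run wins, so identical inputs always
produce bit-identical results (there is no randomness anywhere in the
fitting path).  Standard errors use the standard nonlinear-regression
curvature formula `sigma2 (J'J)^{-1}` with a finite-difference Jacobian; a
singular information matrix yields flagged `NA` SEs.  Degenerate inputs
(constant rates, fewer than 4 distinct temperatures, `n < p + 2`) return a
flagged non-convergence with a diagnostic.

## The four metrics and the weights

Adjusted R², the refined index of agreement (absolute-error based, scaling
constant `c = 2`, range `[-1, 1]`), and Akaike and Schwarz weights.  The
information criteria come from the Gaussian likelihood with profiled
variance, `n log(sse/n)`; AICc is used instead of AIC because at `n = 42`
the parameter count exceeds `n/40` for every model.  The default parameter
count is `K = p + 1` (regression parameters plus the error variance, the
standard least-squares convention); `fit_config(ic_param_count =
"regression_only")` reproduces the `K = p` convention.  Because weights are
functions of criterion *differences* only, the two conventions differ only
through the K-dependent part of the AICc correction, and in this design the
choice does not alter rankings materially.  A perfect fit (`sse = 0`)
propagates as a `-Inf` sentinel that takes the whole weight (split on
ties) — this makes noiseless-recovery dominance exact rather than a
floating-point accident.

## Selection

For each treatment the twelve weights (each kind) sum to 1; averaged over
treatments they yield a mean `w_A` and `w_B` per model.  The goodness set is
the union of the top-6 by mean `w_A` and top-6 by mean `w_B`.  A treatment
in which a single model's weight exceeds 0.8 dominates the means, so such
treatments are flagged and the means and top-6 sets recomputed without them;
the union is taken over all four lists.  The threshold is configurable, and
a full leave-one-treatment-out sweep is always reported so the robustness of
the outcome is visible rather than asserted.  The meaningful set is read off
the registry flags: closed-form `P_max`/`T_opt`/`T_max` and a finite
`T_max` — i.e. Briere-1, Briere-2, Deutsch, van der Heide, Yan and Hunt.
The best model is the intersection member with the highest mean weight under
every computed criterion; ties fall to the model with fewer parameters, then
alphabetically.  An empty intersection is a reported outcome (`best = NA`
with a diagnostic), not an error.

On the published seven-treatment weight tables shipped with the package
(`reference_weights()`), this procedure flags the *C. serrulata* winter
Moreton Bay treatment (one model's weight exceeds 0.85 there), finds the
same six best models per criterion with and without it, intersects the
resulting seven-model goodness set with the five-model meaningful set to
{Briere-1, Deutsch, Yan and Hunt}, and selects **Yan and Hunt**, which has
the higher mean weight under all four criteria.

## Q10

Below the optimum the rise is summarised by
`P(T) = P_0 * Q10^{(T - T_ref)/10}` fitted by nonlinear least squares to
the observations with `T` *strictly* below `T_opt` (`T_ref = 20` °C by
convention; changing it rescales `P_0` by `Q10^{dT_ref/10}` and leaves
`Q10` invariant, which is tested).  Because `T_opt` is model-dependent, Q10
is computed per model × treatment pair.  Starting values come from the
log-linear regression, which is exact on noiseless data.  The known small
bias from the plateau just below `T_opt` is not corrected: with ~5 °C
spacing between incubation temperatures at most one sub-optimal observation
sits in the plateau region, and the published workflow accepts the same
approximation.

## The synthetic-data generator

No raw measurements are distributed with the study this package emulates,
so the generator is the package's source of test data and defines the
study conditions: 7 treatments (three *C. serrulata*, three *H. uninervis*,
exactly one *Z. muelleri*), 7 incubation temperatures (15–43 °C winter,
17–43 °C summer, endpoints fixed, interior approximately even), 6
replicates (n = 42), true curves from the Yan and Hunt model at the
published fitted parameter scales (`reference_parameters()`), and additive
homoscedastic Gaussian replicate noise with SD 0.3 mg C g⁻¹ DW h⁻¹ — a
deliberate, simple structure consistent with unweighted least squares and
with the magnitude of replicate scatter visible in published
photosynthesis–temperature figures.  A per-temperature SD vector is
supported for heteroscedastic scenarios.  The `skew = "positive"` scenario
mirrors the true curve about `T_opt` before sampling, emulating the
sharp-rise/gradual-fall shape reported for *Z. muelleri*; under it the Yan
and Hunt model demonstrably loses weight to more flexible forms, which is
the qualitative caveat the tests reproduce.

What the generator does *not* emulate: temperature-dependent error
variance, within-replicate correlation (the same leaf measured across
temperatures), instrument drift, and any systematic lack of fit between a
real curve and the Yan and Hunt family.  Passing tests therefore
demonstrate correctness of the estimation and selection machinery under the
stated statistical model, not robustness to violations of it.

## Numerical choices

Problem sizes were chosen so the full suite runs in about a minute: the
end-to-end simulation check uses 20 seeded studies of 7 treatments × 12
models, the SE-calibration check 200 single-model refits, and the grid
oracle 21³ points per model.  Roots are polished to 1e-6 °C; optimum
identities are asserted at 1e-9 relative; noiseless self-recovery at 1e-4
relative; comparisons against published 4-dp table values at 1e-4
*absolute*, since means of rounded cells can differ from means of unrounded
values by up to half a unit in the last place.  Seeds are fixed in every
stochastic test; fitting itself is deterministic.

## Limitations

* `T_max` estimates extrapolate beyond the warmest design temperature and
  are sensitive to the single 43 °C level; `T_opt` interpolates and is much
  better constrained.  The same asymmetry will hold for any data on this
  design.
* The registry's capability flags encode the selection semantics (which
  models count as yielding meaningful parameters); alternative judgements —
  e.g. trusting O'Neill's `T_max` — can be explored by flipping flags on a
  copied registry, and the selection layer honours them.
* The four-parameter Yan and Hunt variant (free `T_min`) is out of scope,
  as is any mechanistic interpretation of the fitted energies in the
  Johnson form.
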