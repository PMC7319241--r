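---
title: "Feedback strength, hysteresis and dynamic regimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback strength, hysteresis and dynamic regimes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oefsim)
```

This vignette documents the scientific content of `oefsim`: the minimal
ecosystem model and its bistability analysis, the two response statistics
(absolute nonlinearity and hysteresis), the synthetic microcosm generator,
and the regime-detection pipeline, together with the numerical and design
choices that a user should know before trusting or changing the defaults.

## The minimal ecosystem model

The package's theoretical core is the one-dimensional ecosystem model

$$\frac{dY}{dt} = a - bY + r\,f(Y), \qquad f(Y) = \frac{Y^p}{Y^p + h^p},$$

where $Y \ge 0$ is an aggregate ecosystem property (think dissolved oxygen
or biomass in a pond), $a$ an environmental driver that promotes $Y$, $b$
the decay rate, $r$ the self-replacement rate, and $h$ the threshold around
which the sigmoidal self-replacement saturates. The exponent $p$ sets the
steepness of $f$ and is read as the strength of the positive
organism-environment feedback: at $p = 0$ the system is linear, and as $p$
grows the feedback becomes switch-like. The reference configuration fixes
$b = r = h = 1$ and varies $p$ between 0 and 10.

Two conventions are worth making explicit:

* **$f$ at $p = 0$.** The expression $Y^0/(Y^0 + 1)$ equals $1/2$ for every
  $Y > 0$ but is formally $0^0/(0^0+1)$ at the origin. We define
  $f \equiv 1/2$ for $p = 0$ at all $Y$, the continuous limit; the $p = 0$
  model is then the linear system $dY/dt = a + 1/2 - Y$ whose closed-form
  solution is used as an integrator oracle in the tests.
* **Large $p$.** $f$ is evaluated on the $(Y/h)^p$ ratio scale so that
  exponents in the thousands saturate to 0/1 instead of overflowing.

### Equilibria, folds, and the critical exponent

For fixed $a$ the equilibria are the roots of $g(Y) = a - bY + rf(Y)$ on
$[0, (a+r)/b + 1]$; the upper bound holds because $f \le 1$. Roots are
located by a dense sign scan (10 000 points by default) refined with
bisection, and classified as stable where $g$ crosses from positive to
negative. Because the scan can land exactly on a root, grid zeros and
bracketed roots are de-duplicated at a fraction of the grid spacing. The
interval of driver values with more than one stable equilibrium --- bounded
by the two fold (saddle-node) bifurcations --- is found by scanning $a$ and
bisecting on the stable-state count to $10^{-6}$.

With $b = r = h = 1$ the onset of bistability has a closed form: multiple
equilibria require $\max_Y f'(Y) > 1$, and the maximizer of $f'$ satisfies
$Y^p = (p-1)/(p+1)$, giving the tangency margin

$$\phi(p) = p\left(\frac{p-1}{p+1}\right)^{(p-1)/p}
  \left(\frac{p+1}{2p}\right)^2 - 1,$$

whose root `critical_p()` returns ($\approx 3.717$). The package checks this
closed form against the purely numerical empty-to-nonempty transition of
`bistable_interval()`; on an integer grid of $p$ the first bistable value is
4, which is why fold-type shifts are only expected at feedback strengths
above about 4.

### Forced simulation

`simulate_model()` forces the model with a triangular driver ramp: $a$ runs
linearly from one extreme to the other in `total_steps / 2` unit timesteps
and back. The reference rates are 200 steps (fast: comparable to the
system's $O(1/b)$ relaxation time) and 20 000 steps (slow:
quasi-static). Integration uses classical fixed-step fourth-order
Runge-Kutta with 10 substeps per unit timestep and the piecewise-linear
driver evaluated at the stage times. The step is far inside the stability
region (the stiffest local rate is $O(1)$), and the tests verify that
halving the substep changes trajectories by less than $10^{-7}$. The
initial state defaults to the lowest stable equilibrium at the starting
driver value, so an up-sweep starts on the lower branch and a down-first
sweep starts on the branch stable at the high driver value.

Under a slow ramp with $p$ above the critical exponent the trajectory tracks
a stable branch until the fold and then jumps; because relaxation slows
critically near a fold, the jump lands slightly *past* the fold driver value
(about $3 \times 10^{-3}$ driver units at 20 000 steps), which the tests
assert as a one-sided bound rather than exact equality.

## The two response statistics

Both statistics operate on a *driver-response path*: state values against
driver values with each point labelled ascending or descending.

**Absolute nonlinearity** is the root-mean-square difference between the
fitted values of a penalized cubic regression spline and of an ordinary
least-squares line, both fit to one phase of the path. The smoother is
`mgcv::gam` with a cubic regression spline basis (dimension 10, reduced when
fewer distinct driver values are available) and smoothness chosen by
generalized cross-validation --- the package's default smoother choices.
Because straight lines lie in the penalty null space, noise-free affine data
give exactly the line back and the statistic is zero. The response is not
standardized: the statistic is in state units (absolute nonlinearity), is
invariant to adding a constant, and scales linearly with the state. Basis
dimension and the matching tolerance are arguments, not constants.

**Hysteresis** is the mean absolute difference between ascending-phase and
descending-phase states paired at equal driver levels. The pairing
conventions are:

* driver levels observed repeatedly within a phase are averaged first, so
  the number of pairs stays interpretable;
* the *turning extreme* --- the driver value at which the sweep reverses
  (the temperature plateau in the experimental schedule, the high driver
  extreme in an up-first model sweep) --- is excluded;
* remaining levels present in both phases are matched exactly; if no exact
  matches exist (asymmetric grids) the descending path is linearly
  interpolated onto the ascending levels interior to its range. Exact
  matching is the default dialect; interpolation is the fallback.

For a symmetric simulated ramp of $T$ steps this yields $T/2$ pairs
(the start level pairs too); for the stepped experimental schedule it
yields one pair per temperature level below the plateau --- fifteen pairs
at $15, 15.7, \ldots, 24.8$ degrees.

A useful distinction the sweep makes visible: a slow ramp only shows
hysteresis when genuine alternative stable states exist, whereas a fast
ramp also shows *apparent* hysteresis --- up/down divergence caused by
transients lagging the driver --- which grows with feedback strength even
below the critical exponent and exceeds the slow-ramp hysteresis at equal
$p$. The sweep (`run_sweep()`) records nonlinearity of both phases,
hysteresis, and the maximum stable-state count for every combination of
$p$, ramp length and direction; failed cells are recorded with their error
message rather than aborting, and results are independent of evaluation
order.

## The synthetic microcosm generator

No experimental dataset ships with the package; `generate_experiment()`
emulates the design that motivates the analysis pipeline so that every
downstream stage is testable. The emulated design is 5 gas-exchange
treatments $\times$ 6 replicates of a bacteria - two ciliate prey - one
ciliate predator community in sealed jars, sampled every 2 days under the
stepped 15 to 25 to 15 degree protocol (0.7 degrees every 2 days for 30
days, a 7-day plateau, mirror-image descent; the nominal 25.5 degree peak is
capped at 25). Communities start near 10 %O2 in the liquid, $10^6$
bacteria/ml, 1000 prey/ml and 10 predators/ml.

State per microcosm: liquid and headspace oxygen on the sensor scale on
which atmospheric equilibrium reads 21 %O2 (a single scale in both
compartments, modelling exchange as relaxation toward equality rather than
Henry-law partitioning), bacteria, two prey pools, predator density and a
cyst-pool flag. The daily-rate model, advanced by Euler-Maruyama steps of
0.1 day with multiplicative lognormal environmental noise on the biotic
rates:

* bacteria grow logistically (carrying capacity $2 \times 10^6$/ml,
  emulating the slow-release nutrient source) and are grazed by prey;
* prey growth saturates in bacteria, is limited by a shared carrying
  capacity, and follows an asymmetric thermal performance curve (optima 24
  and 25 degrees for the two pools, broad below and sharp above the
  optimum); mortality includes a heat term active above 23.5 degrees whose
  magnitude is set by the replicate's latent thermal tolerance (below);
* predation is a saturating functional response multiplied by an oxygen
  limitation factor $O/(O + K_O)$, $K_O = 4$ %O2; a small prey refuge
  (30/ml per pool) keeps predation from annihilating prey on its own;
* the predator has a lower thermal optimum (20 degrees) with a sharp
  decline above 23 degrees plus a heat-mortality term, an
  interference-capped background mortality, and hypoxia mortality below 4
  %O2 --- the predator, the largest organism, is the one intolerant of low
  oxygen;
* community respiration drains liquid oxygen in proportion to a weighted
  sum of the standing stocks with a $Q_{10} = 2$ temperature scaling;
  oxygen diffuses between liquid and headspace, and the headspace exchanges
  with the atmosphere at the treatment's rate ($k_{atm} = 20$/day when
  open, a 0.08/day leak otherwise, since no jar is perfectly sealed);
* the air-addition treatments get a service event every 2 days that moves
  the headspace toward atmospheric by fractions 0.8 / 0.5 / 0.3 (200, 100,
  50 ml added to a roughly 150 ml headspace) and the bubbled liquid by 0.3
  times those fractions;
* densities below an extinction floor are zeroed; the floor is absorbing
  for bacteria and prey, while the predator encysts and re-emerges when
  prey recover past 200/ml.

**Planted regimes.** Replicate divergence is driven by a latent per-replicate
thermal-tolerance draw: with a treatment-dependent probability (0, 0.15,
0.20, 0.35, 0.80 from open to closed) the prey pools are heat-tolerant and
survive the plateau; otherwise the heat mortality extinguishes them. The
draw is a reduced-form summary of the rescue mechanisms that favour
persistence under strong feedback (oxygen-limited predation releasing prey),
and the probabilities were chosen to mirror the kind of cluster composition
such experiments report, increasing monotonically with feedback strength.
The drawn regime --- persistence (the low-oxygen regime) versus functional
extinction --- is recorded per microcosm as hidden ground truth, which is
what makes the generator usable for validating the clustering stage. The
dynamics that follow from the draw are mechanistic: tolerant prey boom at
the plateau once the heat-stressed predator collapses, the boom's
respiration drags oxygen down wherever exchange is weak, low oxygen then
keeps the recovering predator suppressed (limited predation plus hypoxia
mortality), and the low-oxygen state self-maintains --- exactly the positive
feedback loop the treatments are meant to strengthen. In strongly ventilated
jars the same boom is re-controlled by the predator and oxygen recovers.

**Reproducibility.** Each microcosm runs on an independent substream seeded
deterministically from the root seed and the (treatment, replicate)
position, so regenerating with more replicates never changes existing ones.
With noise switched off the dynamics are deterministic, replicates within a
treatment are identical, and each treatment expresses its majority regime.

**What the generator does not emulate.** Parameter values are config
defaults producing the qualitative phenomenology, not estimates of any real
system; there is no video tracking or flow-cytometry observation model
beyond lognormal density noise and Gaussian morphology draws; medium
replacement at sampling (1% of volume) is ignored; the two prey species
differ only in thermal optimum, not in oxygen response, because
species-level oxygen responses are unknown; and real experiments contain
slow drifts (nutrient depletion, evaporation, wall growth) that the
generator omits. Passing the pipeline on synthetic data therefore shows the
*methods* are sound and sensitive under the planted contrast --- not that
real microcosms must behave this way.

Biomass observations compose density with ellipsoid biovolume
$(4/3)\pi (a/2)^2 (b/2)$ from individual width/length draws (the morphology
symbols $a, b$ are the conventional width/length names and are unrelated to
the model's driver and decay rate).

## Regime detection and group comparisons

Time-series dissimilarity uses classic dynamic time warping: unconstrained
monotone alignment, absolute local cost, symmetric steps. DTW is symmetric
with zero self-distance but violates the triangle inequality, so it is used
as a dissimilarity, never as a metric. Series are standardized (centred,
unit standard deviation; constant series map to zeros) before DTW by
default --- the shape, not the level, should drive the clustering --- and a
Sakoe-Chiba window is available but off by default. The implementation is
the textbook dynamic program and is checked in the tests against exhaustive
enumeration of all warping paths on short series.

Clustering is agglomerative with Ward's criterion on squared
dissimilarities (`stats::hclust`, method `ward.D2`, the modern Ward
dialect; `ward.D` is available as an option since the alternative dialect
exists in the literature), cut at $k = 2$ clusters by default because the
question is the presence of *two* alternative regimes; $k$ is an argument.
Cluster identities are anchored to be reproducible: for dissolved oxygen,
cluster 1 is the cluster with the higher mean raw series (the stabilized
regime); for biomass, cluster 1 has the lower mean. The two per-variable
labelings combine into joint codes A (1,1), B (2,1), C (2,2), with the
fourth combination reported as "other".

The cluster-treatment association is tested by the likelihood-ratio
(deviance) test of a Bernoulli model with one probability per treatment
against the constant-probability null. With a categorical predictor the
alternative's maximum likelihood is the group proportions, so the deviance
has a closed form (with $0\log 0 = 0$) identical to the logistic-regression
likelihood-ratio test; the chi-squared reference uses levels $- 1$ degrees
of freedom. Group comparisons of the metrics use `stats::lm`/`anova`:
one-way ANOVA on the treatment factor, additive ANCOVA when the cluster
factor is added, sequential F tests, and the interaction only on request;
zero residual variance is reported as an undefined F rather than an error.

## Problem sizes and runtime choices

The test and acceptance workloads are sized to run comfortably on a single
CPU: the feedback sweep uses the full grid $p = 0, 0.5, \ldots, 10$ at both
200 and 20 000 steps; bistability scans use 101-201 driver values with
$10^4$-point root scans; the synthetic validation uses 20 independent
experiments of 30 microcosms each (the clustering quality is summarized as
the mean adjusted Rand index across those 20 experiments), and the
DTW matrices are $30 \times 30$ over 34-point series. These sizes give
stable qualitative results; all of them are function arguments that scale
up if sharper estimates are wanted.

## Known limitations

* The minimal model is scalar; nothing here does multi-dimensional
  bifurcation continuation, stochastic versions of the minimal model, or
  early-warning indicators.
* The nonlinearity statistic inherits the smoother's behaviour: with very
  few points per phase the spline basis shrinks and the statistic loses
  sensitivity to genuine curvature.
* Hysteresis measured under a fast ramp conflates transient lag with true
  path dependence by design; only the slow-ramp limit isolates
  bistability-driven hysteresis.
* The generator's regime planting makes the clustering validation a
  *recovery* test with known truth; it cannot tell how often real
  replicate divergence would be missed.
* DTW clustering at $k = 2$ will split something even when only one regime
  is present; interpret cluster sizes, the association test and the
  dendrogram together.
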