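---
title: "Modeling nutrient uptake and biomass formation in BY-2 suspension cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nutrient uptake and biomass formation in BY-2 suspension cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(by2growth)
```

## The system and the models

Tobacco BY-2 suspension cells grown in stirred-tank bioreactors convert
sucrose, ammonium, nitrate and phosphate into biomass. `by2growth`
implements two unstructured segregated Monod-type models of that process.
Both split the dry mass (DM) into an active fraction $X_a$ and a dead
fraction $X_d$ with irreversible conversion,

$$\frac{d(X_a V)}{dt} = (\mu - k_d)\,X_a V, \qquad
  \frac{d(X_d V)}{dt} = k_d\,X_a V, \qquad \frac{dV}{dt} = F_t ,$$

where $\mu$ is the specific growth rate, $k_d$ the death rate constant and
$F_t$ the feed rate. Every nutrient kernel is a paired
saturation–inhibition Monod factor

$$f(c; K, K_I) = \frac{c}{c + K}\cdot\frac{K_I}{c + K_I},$$

which is bounded by 1, reduces to plain Monod saturation as
$K_I \to \infty$, and has maximum $1/4$ at $c = K$ when $K_I = K$
(`monod_factor()`).

**Initial model** (12 parameters, `params_initial()`): growth is the
product of sucrose, ammonium and nitrate factors,
$\mu = \mu_m f(S) f(A) f(N)$. Each nutrient is consumed at its own rate
$\mu_r f(r) X_a$. Phosphate is tracked but deliberately excluded from the
growth product: it is depleted within about three days, and a
multiplicative phosphate factor would wrongly zero the growth from then
on. Its uptake $\mu_P P$ is likewise independent of the biomass — the
concentration is near zero for most of the run, where a
biomass-proportional term is numerically fragile and adds an
unidentifiable parameter.

**Improved model** (20 parameters, `params_improved()`): sucrose is not
taken up directly but hydrolysed by cell-wall invertases at rate
$\alpha f(S) X_a$ into fructose and glucose, each produced at
$m_{SF} = m_{SG} = 0.526$ g per g sucrose. These yields are stoichiometric
constants (the hexose/sucrose molar-mass ratio, $180.16/342.30$), never
fitted. Growth depends on the hexoses additively,
$$\mu = \Big(\mu_m + \mu_{mA}\tfrac{A}{A+\delta_A}
        + \mu_{mP}\tfrac{P}{P+\delta_P}\Big)\,
  \big(f(G) + f(F)\big)\, f(N),$$
with ammonium and phosphate entering the maximum rate as additive terms so
their depletion attenuates rather than abolishes growth. The offsets
$\delta_A, \delta_P$ — interpretable as the minimal concentrations at
which the corresponding growth contribution is still near its maximum —
are fixed at 10% of the design's starting ammonium and phosphate, stamped
onto the parameter object by `with_growth_offsets()` (and re-derived per
design inside calibration). The hexose pair $f(G) + f(F)$ is used exactly
as stated, without renormalisation; its maximum is $0.5$.

### Units

Internally every species is carried in g L$^{-1}$, because the saturation
and inhibition constants of both reference parameter sets are reported in
g L$^{-1}$. Millimolar values appear only at the I/O boundary, bridged by
a per-nutrient molar-mass table (`molar_masses()`). The inorganic
nutrients default to free-ion masses (NH$_4^+$ 18.04, NO$_3^-$ 62.00,
PO$_4$ 94.97 g mol$^{-1}$) since the assays quantify dissolved ions; the
sucrose bridge (88 mM $\leftrightarrow$ 30 g L$^{-1}$) validates the
convention for sugars, and the table is overridable for anyone preferring
salt equivalents.

## Process simulation

`simulate_culture()` integrates either model with `deSolve::lsoda`
(relative tolerance $10^{-8}$, absolute $10^{-10}$ by default —
near-depletion nutrient dynamics are stiff). A batch phase runs with
$F_t = 0$; in semi-continuous mode the fresh-mass trigger (default
100 g L$^{-1}$ FM at 20 g FM per g DM) is located by `lsodar` root
detection, after which the capacitance-probe feed loop is abstracted to a
setpoint-holding law $F_t = \mu X_a V / X_{set}$ (the paper gives no
transfer function for the controller, so the simulator holds the dry mass
at the setpoint exactly, which is what the controller achieves at steady
state). Broth is drained back to the starting volume on a fixed interval
(default 24 h inside the reported 22–26 h window), modeled as an
instantaneous well-mixed removal: volume drops, concentrations are
continuous.

Negative-concentration protection: the right-hand sides evaluate every
Monod factor at $\max(c, 0)$, so consumption shuts off as a species hits
zero, and any residual integrator undershoot is clipped in the stored
trajectory. The dead-mass balance includes feed dilution
($d(X_d V)/dt = k_d X_a V$), a declared choice: only the active-mass
balance is stated in the source material, and this form conserves the
total-mass bookkeeping.

`peak_active_yield()` extracts the peak of active DM from the dense grid
and refines it with a quadratic through the three bracketing points; the
dimensionless yield is $Y_a^* = X_a(t^*)/X_0$. Halving the solver
tolerances moves $(t^*, Y_a^*)$ by well under 0.1%.

## Calibration

`fit_model()` minimizes the weighted least-squares objective on relative
residuals,
$$Q(\theta) = \sum_h \sum_t \sum_r w_r
  \Big[1 - \frac{g_r(\theta; t)}{\tilde y_{h,t,r}}\Big]^2,$$
with unit weights by default. Because the form divides by the measured
value, observations below a per-response floor (the constant uncertainty
$u^0_r$ if positive, else $10^{-6}$) are excluded — late-time phosphate
readings are effectively zero and would otherwise destroy the objective.
A simulation failure at a trial $\theta$ returns a large finite penalty
($10^{10}$) instead of an error so optimizers can pass through.

The optimizer is bound-constrained `L-BFGS-B` run in range-normalized
coordinates: the identifiable parameters span four orders of magnitude
(e.g. $k_d \sim 10^{-4}$ vs $\mu_m \sim 10$), and finite-difference steps
must be relative to each parameter's identification range to resolve the
optimum. One-dimensional problems use Brent bracketing instead. The
problem is nonconvex, so fits default to 16 Latin-hypercube starts plus
the baseline. The constraint that each inhibition constant stays at or
above its saturation partner ($K_{Ir} \ge K_r$, enforcing an activity
plateau rather than spurious high-substrate suppression) is built into the
parameterization: when both are free the optimizer works on the shift
$d = K_I - K \ge 0$; when only one is free the partner's fixed value
tightens the box directly. Fits report which pairs ended on the boundary
(`constraint_active`), since in practice identified inhibition constants
sit essentially on their saturation partners.

### Measurement error and bootstrap intervals

Each response carries a constant plus proportional uncertainty,
$\sigma_{h,t,r} = u^0_r + u^\%_r\,\tilde y_{h,t,r}$ (`error_matrix()`),
with study defaults of 3% for dry mass and 6% for every nutrient and no
constant part (the per-assay constants live in unpublished supplementary
material).

`bootstrap_ci()` builds confidence intervals by residual bootstrap:
standardized residuals $(\tilde y - g)/\sigma$ are pooled per response
across experiments and times, resampled with replacement, inflated by the
small-sample factor $\sqrt{n/(n-p)}$, rescaled by the local $\sigma$, and
added back onto the fitted predictions; each synthetic dataset is
refitted and the percentile interval (90% by default) is reported. We
also provide the cruder scheme that resamples the $\sigma$ magnitudes
themselves with random signs (`resample = "uncertainty"`); it is not the
default because under strongly proportional errors it transplants the
large early-trajectory error scale onto the small late observations that
carry the most weight in the relative objective, which we measured to
inflate intervals far past nominal coverage on a linear reduction of the
model. With the default scheme, 90% intervals covered the true parameter
in 82% of 50 replicates of that reduction (100 resamples each), inside
the 80–98% acceptance band; zero measurement noise collapses every
interval to a point. One caveat the reduction made visible: the
relative-residual estimator itself carries an $O(\mathrm{cv}^2)$ bias, so
at large proportional noise percentile intervals are mis-centered — a
property of the estimator, not of the resampling.

### Fit quality

`mae()` is the mean absolute error of one response on one dataset;
`nmae()` normalizes by the grand mean of that response over a
normalization set; `mae_subset()` pools observations across experiments.
Conditional variants (e.g. dry mass above 8 g L$^{-1}$, the regime where
the initial model breaks down) are expressed as observation filters.

## Cross-validation

`kfold_compare()` performs leave-one-experiment-out cross-validation:
folds are whole experiments, never splits within a time series. For each
fold every candidate model is refitted on the remaining experiments and
scored on the held-out one; `aMAE` is the plain mean of the fold MAEs and
`anMAE` divides by the response's grand mean. An improved-model candidate
refuses datasets lacking fructose/glucose measurements, mirroring why the
first three standard-condition runs cannot enter such a comparison. On
synthetic studies generated from the improved model at study noise, the
improved model won the dry-mass `anMAE` comparison in 20 of 20 seeded
replicates (margins 16–40$\times$ at the reduced scale used in the test
suite).

## Bi-criteria optimization

`pareto_front()` trades off the peak yield $Y_a^*$ (maximize) against the
peak time $t^*$ (minimize) over the inoculum $X_0 \in [0.3, 1.5]$
g L$^{-1}$ and initial sucrose $S_0 \in [17, 88]$ mM, with the other
initials pinned at the standard MS start (21 mM ammonium, 39 mM nitrate,
2.7 mM phosphate). Optimization-stage simulations run batch-only: the
design variables are initial conditions, and the relevant experiments ran
their batch stage to sucrose depletion; a config switch
(`feed_policy()`) exposes the semi-continuous alternative.

The front is assembled in three stages:

1. **Anchors** (`anchor_points()`): the maximum-yield design and the
   earliest-achievable-peak design. Each is a coarse 5×5 scan of the
   design rectangle (covering corners and center) polished by one local
   `L-BFGS-B` run.
2. **Weighted-sum sweep** over normalized objectives, which recovers the
   convex part of the front.
3. **ε-constraint pass**: the peak time is held at a uniform grid of
   values between the anchor times (step 3 h; the reference span 96–180 h
   gives exactly 28 steps). The equality $t^*(X_0, S_0) = t_{target}$
   (tolerance 0.5 h) is solved by exploiting that the peak time is
   monotone decreasing in $X_0$ at fixed $S_0$: a root solve in $X_0$
   nested inside a one-dimensional yield maximization over $S_0$. This
   recovers any non-convex section that no positive weight pair can
   reach.

The union is filtered to its non-dominated subset (`nondominated()`). On
a 21×21 brute-force grid of the design space, every front point lies
within one grid cell of the brute-force non-dominated set, and no grid
design dominates a front point beyond the grid's own resolution.

With the identified initial-model parameters the package reproduces the
reported trade-off structure: the maximum yield sits at the
lowest-inoculum/highest-sucrose corner (peak near 183 h, yield near 30
against the reported ≈185 h and ≈27.9 — the offset is consistent with the
reference parameters being printed to 3 significant digits), the earliest
peak (~102 h) requires the highest inoculum, and the interior of the
front holds sucrose near 67 mM — the reduction the study then validated
experimentally.

## Synthetic data

The study's raw trajectories exist only as figures, so `generate_dataset()`
and `make_study()` stand in for the bioreactor: they simulate a design at
chosen "true" parameters, sample every 24 h over a 144 h batch by default
(matching the offline sampling rhythm and the ~6 days to sucrose
depletion), and perturb each value with zero-truncated Gaussian noise of
standard deviation $u^0 + u^\% g$. The Gaussian-with-truncation choice is
ours; the error structure only fixes the magnitudes. The nine in-study
designs are packaged as presets (`study_presets()`), including the
fructose-only and glucose-only carbon-source variants.

What passing tests on such data do show: the estimation, cross-validation
and optimization machinery is correct and internally consistent under the
declared error model. What they do not show: fidelity to features real
cultures have and the generator lacks — autocorrelated probe drift,
model–data mismatch beyond measurement error, FM/DM ratio drift, and any
intracellular nutrient buffering (the study's own stated next step).

## Numerical choices and limitations

- Solver: `lsoda`, rtol $10^{-8}$/atol $10^{-10}$ for production runs;
  reduced-scale analyses in the test suite use coarser tolerances after
  verifying the peak summaries move by <0.1% under tolerance halving.
  The methods-level analyses in this package run at deliberately reduced
  problem sizes (e.g. 50×100 bootstrap replicates on a 13-point linear
  reduction, 20 cross-validation replicates on 3-experiment studies);
  these sizes are stated where they are used.
- Individual $K/K_I$ pairs are weakly identifiable from biomass-level
  data (the classical Monod sloppiness); recovery guarantees in the test
  suite therefore target consumption rates, $\mu_m$, and the practically
  identified growth scale rather than every constant separately.
- The ε-constraint solver assumes the peak time is monotone in $X_0$ at
  fixed $S_0$; this holds across the default design space for both
  reference parameter sets but is re-checked per solve via the bracket,
  and a target is skipped (logged, not fabricated) if the bracket fails.
- Whether dead mass is diluted by feed, and whether the published
  optimization simulated feed or batch, are not stated in the source;
  both choices here are declared above and switchable.
- The min-time anchor is reported from the design-space minimization; the
  source text quotes both ~96 h (derivative-condition anchor) and 102 h
  (front endpoint) — we surface the computed minimum (~102 h at
  $X_0 = 1.5$ g L$^{-1}$) and do not attempt to reconcile the two
  printed values.
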