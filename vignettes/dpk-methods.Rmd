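---
title: "Dermatopharmacokinetic analysis of topical products: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dermatopharmacokinetic analysis of topical products: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpkfit)
```

## The problem

Establishing that two topical drug products are bioequivalent without a
clinical endpoint trial requires surrogate measures of how much drug the
formulation actually delivers into the skin. Two widely used surrogates are
the *in vitro* release test (IVRT, drug release across an artificial
membrane in a Franz diffusion cell) and stratum corneum (SC)
tape-stripping, in which successive adhesive strips remove thin SC layers
whose drug content yields a concentration-depth profile. `dpkfit`
implements the quantitative machinery for both: a mechanistic transport
model for SC uptake, the estimation procedures that recover its parameters
from tape-strip data, TEWL-based thickness measurement, release-kinetics
analysis, and the average-bioequivalence statistics applied to total SC
amounts.

## The uptake model

The SC is treated as a homogeneous membrane of thickness $L$, initially
drug-free, in contact at $x = 0$ with a vehicle of constant drug
concentration $C_{veh}$ and with a perfect sink at $x = L$ (the viable
epidermis). Fick's second law then gives the classical series solution

$$
C(x,t) = K\,C_{veh}\left\{\left(1-\frac{x}{L}\right)
 - \frac{2}{\pi}\sum_{n\ge 1}\frac{\sin(n\pi x/L)}{n}
 \exp\!\left(-\frac{D}{L^2}n^2\pi^2 t\right)\right\},
$$

with two free parameters: the SC-vehicle partition coefficient $K$
(dimensionless) and the diffusivity parameter $D/L^2$ (h$^{-1}$), a
first-order rate constant that fixes the approach to steady state. From
these and an independent thickness measurement follow the permeability
coefficient $k_p = K\,(D/L^2)\,L$ (cm/h), the steady-state flux
$J_{ss} = k_p\,C_{veh}$, the lag time $t_{lag} = L^2/6D = 1/(6\,D/L^2)$,
and the total uptake
$Q(t) = K C_{veh} L\,[\tfrac12 - \tfrac{4}{\pi^2}\sum_{n\,\mathrm{odd}}
n^{-2}e^{-(D/L^2)n^2\pi^2 t}]$, which tends to the triangle area
$K C_{veh} L/2$.

Units are fixed package-wide: depth in um, areas in cm^2, time in h,
amounts in ug, concentrations in ug/cm^3; every conversion is centralised,
and $L$ is converted to cm wherever fluxes are formed.

Numerical choices: the series is truncated adaptively so that the tail
bound stays below $10^{-8} K C_{veh}$ with a floor of 50 terms (convergence
slows as $t \to 0$); residual Gibbs undershoot is clamped at zero because
concentrations are physical; $t = 0$ is special-cased to the exact initial
condition. Correctness is not argued from the formulas alone: the test
suite checks profile, slab amounts and total uptake against an independent
Crank-Nicolson finite-difference solution of the same boundary-value
problem (with implicit-Euler start-up to damp the initial step) to better
than 0.1% across $D/L^2 \cdot t \in [0.01, 5]$, and against adaptive
quadrature.

## Fitting tape-strip profiles

`build_profile()` converts weighed strips to depth via the SC density
(default 1.0 g/cm^3, user-overridable; 100 ug/cm^2 = 1 um at that
density), merges pooled strips -- deep strips are commonly assayed in
groups of up to 4 for sensitivity -- into single depth intervals, and
normalises by the SC thickness. The final strip often slightly overshoots
$L$ because it removes whatever SC remains; bounds are clamped to the unit
interval. A profile whose mass-derived depth exceeds $1.2 L$ aborts: that
almost always means a wrong thickness or density.

`fit_profile()` estimates $(K, D/L^2)$ by least squares. Two decisions
matter here:

* **Interval averages, not midpoints.** The model prediction for an
  interval is its average concentration (slab amount / slab width).
  Pooled deep intervals can span a quarter of the SC, where the profile is
  convex; midpoint evaluation systematically biases $D/L^2$. A test
  demonstrates the superiority on coarse pools.
* **Multi-start bounded optimisation.** The objective is minimised over
  $(\log K, \log D/L^2)$ by L-BFGS-B from a 5 x 5 log-spaced grid
  ($K \in [0.01, 100]$, $D/L^2 \in [10^{-4}, 10]$ h$^{-1}$), keeping the
  best converged start; near steady state the objective is flat in
  $D/L^2$ and single starts are unreliable.

Residuals are unweighted on the concentration scale by default (the
weighting used in the original analyses of such data is not standardised);
`weights = "log"` matches multiplicative assay noise and gives close to
nominal confidence-interval coverage in simulation, and is the better
choice when noise is clearly proportional. Asymptotic standard errors come
from a numeric Jacobian; 90% intervals are t-based, with a seeded
residual-bootstrap alternative.

**Identifiability.** Once $(D/L^2)\,t$ is large the profile is the
steady-state triangle and the data contain no information about $D/L^2$;
the estimate then diverges upward. The fit detects this (series
contribution below numerical noise) and sets `steady_state = TRUE` rather
than reporting a spurious rate. Even short of that limit, $D/L^2$ is
weakly identified: at $(D/L^2)t = 0.3$ the transient signature is a ~3%
deviation from linearity, so 20% assay noise leaves a median relative
error of roughly 50% in $D/L^2$ (quantified by a simulation oracle and
asserted in the acceptance tests), while $K$ is recovered to well under
10%. First strips can be discarded (`discard_first_n`) when surface
cleaning was less rigorous; by default all are kept, since the protocols
this package targets clean the surface before stripping.

## SC thickness from TEWL

Transepidermal water loss rises as barrier is removed, following
$\mathrm{TEWL}(x) = K_w/(H - x)$ to a good approximation; $1/\mathrm{TEWL}$
is therefore linear in the depth removed and its x-intercept is the total
thickness $H$. `fit_tewl_thickness()` performs this inverse extrapolation
by OLS, propagating the intercept's standard error by the delta method.
Readings below twice the pre-stripping baseline are excluded: early
readings are dominated by the still-intact barrier and carry no intercept
information. The estimate is invariant to the TEWL unit scale, exact on
noiseless data, and has <5% median bias at 5% measurement noise (both
asserted). The conventional stripping endpoint -- a reading of at least
100 g m^-2 h^-1, inclusive -- is exposed as
`stripping_endpoint_reached()`.

## IVRT and release kinetics

Receptor sampling with replacement dilutes the receptor, so cumulative
release is reconstructed by mass balance,
$Q_n = (C_n V_r + \sum_{i<n} C_i V_{s,i})/A$ (defaults $V_r$ = 7.4 mL,
$A$ = 2 cm^2). Whether a given laboratory applied this correction is often
unstated; it is switchable (`correct_replacement`). Diffusion-controlled
release from a semisolid follows Higuchi kinetics, $Q \propto \sqrt{t}$;
`higuchi_fit()` is an OLS fit of $Q$ on $\sqrt t$ with an optional
early-burst exclusion (t < 0.25 h). Curves with no quantifiable release
are reported as "no release detected" -- a real outcome for lipophilic
drugs against hydrophobic membranes -- rather than fitted. Formulation and
membrane effects on 6-h cumulative amounts are compared by one-way ANOVA
with Bonferroni-adjusted pairwise t-tests at $\alpha = 0.05$.

## Bioequivalence assessment

Total SC amounts after the uptake phase (stripped immediately after
cleaning) and the clearance phase (stripped after a waiting period,
conventionally 17 h) are summarised per product, and products are compared
on the combined [uptake + clearance] pooled sample. The test/reference
ratio of combined means carries a 90% CI; the regulatory verdict is
`equivalent` only if the whole interval lies within 0.8-1.25. The weaker
statement that the *point estimate* lies within the limits is reported
separately (`point_within_limits`) -- the two should not be conflated, and
published analyses sometimes mean only the latter.

CI construction is a seeded percentile bootstrap over replicates (10,000
resamples by default): per-phase summary intervals in this literature are
markedly asymmetric, which a raw-scale t-interval cannot produce, and the
exact construction used in published tables is typically unstated. A
log-t interval is offered as the alternative; raw-scale and log-scale
ratios agree within a few percent at moderate CV (asserted in tests). The
verdict logic is monotone: widening an interval can only demote a verdict.

A worked arithmetic note: combining published per-product uptake and
clearance means with equal weight reproduces a printed
Perrigo-type/reference ratio of 1.015 (printed as 1.02), but the analogous
Taro-type combination gives ~1.12 where 0.99 was printed; that published
value is not recoverable from the summary means by any combination
implemented here, and the package simply reports what it computes.

## The synthetic-data generator

Every estimator above is validated against virtual experiments with known
truth (`generate_tape_strip_cohort()`, `generate_clearance_arm()`,
`generate_release_curves()`), pure functions of a spec and a seed. The
generator emulates the study designs the package targets: 6-h application;
per-replicate $K$ and $D/L^2$ drawn log-normally around the truth
(median-preserving); strip masses log-normal (median 75 ug/cm^2, CV 30%)
drawn until the cumulative depth spans the SC, which lands strip counts in
the protocol-typical 8-30 range; pooling of strips beyond the eighth in
groups of up to 4; multiplicative assay noise per assayed unit; TEWL
emitted from the inverse-thickness law with additive noise and truncated
at the 100 g m^-2 h^-1 endpoint; IVRT concentrations emitted by inverting
the sampling mass balance so the bookkeeping round-trips exactly.

Noise magnitudes are fixed once, at values typical of controlled ex-vivo
work on dermatomed skin from a single source: between-replicate CV 0.20 on
$K$ and $D/L^2$, assay CV 0.15, TEWL noise 5%. Presets:

* `"BMV-ME-like"` / `"BMV-MCT-like"`: a potent corticosteroid in two
  vehicles at equal thermodynamic activity ($C_{veh}$ = 9300 and
  1700 ug/cm^3), $K = 2$ for both, $D/L^2$ = 0.02 and 0.0126 h$^{-1}$,
  n = 6. The diffusivities keep the 6-h profile usefully short of steady
  state (the MCT value corresponds to a ~13 h lag time) and put the true
  flux ratio at ~8.7-fold -- the magnitude of vehicle effect these
  experiments are expected to resolve.
* `"EN-like"`: an antifungal 1% cream cohort ($C_{veh}$ = 10,000
  ug/cm^3, $K = 0.43$, $D/L^2 = 1/78$ h$^{-1}$, n = 14), giving a true
  6-h SC uptake of ~2 ug/cm^2.

The clearance arm has two modes: `"none"` reproduces the ex-vivo
observation that a lipophilic drug does not deplete from excised SC (no
functioning microcirculation beneath it), and `"first-order"` scales
amounts by $e^{-k_{clear} t_{clear}}$ to emulate in-vivo-like elimination
(e.g. a 30% fall over 17 h); the pipeline must, and does, detect both
outcomes.

What the generator does *not* emulate: follicular transport, vehicle
evaporation or metamorphosis, drug metabolism, inter-site anatomical
variation, correlated strip-to-strip assay drift, or finite-dose
depletion. Passing tests therefore demonstrate the correctness of the
estimators under the stated noise structure, not the field performance of
tape-stripping on real skin.

## Problem sizes and determinism

Simulation-backed assertions use fixed seeds and deliberately moderate
sizes: 200 replicates for parameter recovery, 500 for thickness bias,
1000 for CI coverage, 50 virtual studies for each end-to-end operating
characteristic. These sizes give Monte-Carlo standard errors comfortably
inside the asserted margins. Every stochastic operation takes an explicit
seed and restores the caller's RNG state.

## Known limitations

* The uptake model is infinite-dose, single-layer and sink-bounded:
  depleting donors, SC/viable-epidermis bilayers and follicular shunts
  are out of scope.
* $D/L^2$ is intrinsically poorly identified from a single late profile;
  report it with its interval, or design for earlier sampling.
* Equivalence power at high variability is limited: with per-observation
  CV near 40% and 28 observations per product, the 90% CI is wide enough
  that a truly identical pair passes the 0.8-1.25 criterion in well under
  half of repeats. This is a property of the design, not of the
  estimator; the package reports it honestly rather than narrowing the
  interval.
* The bootstrap CI treats replicates as exchangeable; paired or
  crossover designs would need a different resampling scheme.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_preset("BMV-ME-like")
cohort <- generate_tape_strip_cohort(spec, seed = 42)

fits <- lapply(cohort$replicates, function(r) {
  H <- fit_tewl_thickness(r$tewl)$H
  prof <- build_profile(r$records, L = H, t_exposure = 6, Cveh = 9300)
  fit_profile(prof)
})
summarize_replicates(fits)
```
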