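---
title: "Methods: piecewise SEM and climate projection for a desert food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piecewise SEM and climate projection for a desert food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desertSEM)
```

## The estimation problem

The package models a spinifex-grassland food web observed through four
monitoring streams with very different grains: grid-level pitfall
trapping over two decades, grid-level vegetation scoring on the same
trips, site-level monthly camera trapping over two years, and daily
station rainfall. A single covariance-based structural equation model
cannot absorb that mixture of dataset lengths, distributions and random
effects, so the causal network is estimated *piecewise*: each of nine
endogenous variables gets its own local regression, and the network is
the union of the 26 fitted directed effects. `canonical_graph()` encodes
this structure once; everything else (fitting, path standardization,
projection) is generic over it.

Two reading conventions matter:

* **Edges are predictor terms.** A categorical predictor (site, in the
  dasyurid model) and an interaction (`phase:dingo_rate` in the
  mesopredator models) each count as one directed effect, which is how
  the nine formulas sum to 26.
* **Rate covariates are exogenous measurements.** The graph contains
  both rodents → predators (numerical response) and predators → rodents
  (suppression). These are not a cycle: the predictor in each direction
  is an effort-standardized *rate* (captures per 100 trap-nights,
  photographs per camera-night) measured by a different stream than the
  response it explains. Only cover → seed → rodents, where a node's
  response column literally feeds the next model, are treated as
  endogenous dependencies; they fix the propagation order.

## The node model and its fitter

Every node is a GLMM with one scalar random intercept on the sampling
occasion:

* Poisson, log link, `offset(log(effort))` for all count nodes;
* binomial, logit link for the two vegetation scores. Cover is modelled
  as successes out of 100 and the seed index out of 5 — these are
  grid-averaged scores, not integer trials, so the likelihood uses the
  continuous (lgamma) binomial kernel and non-integer "successes" are
  accepted. The denominators are the only ones compatible with the score
  ranges (0–100 %, 0–5).

Estimation (`fit_node()`) is penalized IRLS over the fixed effects and
the occasion intercepts jointly at fixed SD, with the random-intercept
SD chosen by a one-dimensional search maximizing the Laplace marginal
log-likelihood; because the random design is a group indicator, the
Laplace correction only needs the per-group sums of IRLS weights, and an
adaptive Gauss–Hermite refinement of the integral is available through
`glmm_control(agq = )` for anyone worried about the Laplace
approximation at small counts. Numerical choices:

* inner iterations stop at a relative penalized log-likelihood change of
  `1e-8` (max 500); step-halving enforces a monotone penalized
  log-likelihood, which the tests assert on every stored trace;
* the SD search runs on `log(SD)` over `[1e-4, 10]`; an optimum below
  `1e-3` is declared singular, warned about, and refitted at exactly
  SD = 0 — at which point the scheme *is* ordinary IRLS and agrees with
  `stats::glm` to machine-level accuracy (this is also the package's
  oracle test for the fitter);
* the optimizer is deterministic from the zero start, so fits carry no
  seed;
* Wald inference throughout: `p = 2Φ(−|z|)`, with a joint χ² Wald test
  for multi-column (factor) terms. Likelihood-ratio tests would be a
  reasonable alternative; Wald was chosen and is stated on the output.
* linear predictors are clamped to ±30 inside the IRLS weights purely to
  avoid overflow during early iterations.

The red fox node is fitted on centred, unit-SD covariates (its raw
covariates are badly scaled for a joint Newton step); `coef_raw_scale()`
maps estimates and covariance back, exactly, because the z-design spans
the same column space — interactions included.

**Deviance explained.** Mixed-model deviance is taken as −2 × the
Laplace marginal log-likelihood, for the fitted model and for a null
that keeps the offset and the random intercept but drops all fixed
predictors, on identical rows. The ratio `(D_null − D_fit)/D_null` is
then in [0, 1] up to optimizer tolerance because the null is nested.

**Standardized paths.** A path's effect size is the change in the
predicted response (natural scale, random effect at zero, offset at its
mean log-effort) between the predictor's observed minimum and maximum,
holding every other design column at its observed mean, divided by the
observed response range. Design choices, each of which had defensible
alternatives: other columns are held at *means* (the conventional
choice); the divisor defaults to the *observed* range with the
theoretical range selectable for binomial nodes; interactions are swept
over the interaction column itself; factor terms report the spread of
their level predictions (sign-less by construction, so the path table
stores `NA` for their raw coefficient). The sweep is deliberately a pure
two-point evaluation of the prediction function, so an independent
re-evaluation at the two extreme points is an exact oracle for it.

## The synthetic study

`simulate_dataset()` exists so that estimation and projection can be
tested against known truth; its defaults are the study conditions, not
tuning knobs.

* **Design**: 9 sites; grids per site uniform on 2–12; 36 pitfall traps
  per grid with 2–6 trapping nights per trip (72–216 trap-nights);
  trips synchronized across sites on a shared calendar; a camera window
  covering the final 24 months. The default of 25 trips per site (three
  per year) keeps the pooled capture tables near the scale of the
  field study's larger submodels (~1 500 grid × trip rows) while letting
  a 100-replicate recovery run finish in minutes; the field program ran
  up to 130 trips per site.
* **Rainfall** is a two-part daily process: wet-day probability 0.10 and
  integer wet-day totals `1 + NB(mu = mean_event − 1, size)` with
  `mean_event = 5` mm — chosen so the implied median annual total
  (~180 mm) sits inside the range of long-term station medians for the
  region, with a heavy right tail at the default `size = 1`. The `size`
  parameter has a clean light-tailed limit (event-size variance →
  `mean_event − 1`) used by the moment tests. Mean event sizes below
  1 mm are rejected — the model works in integer millimetres.
* **Wildfire** history is per grid: an annual burn probability of 1/26
  (the regional mean return interval) plus staggered initial ages drawn
  NB(mean 20, size 3.34). Making fire grid-level rather than site-level
  is a deliberate choice: fire scars are patchy at the sub-site scale,
  and it gives the years-since-fire covariate genuine within-trip
  replication so that the node models' standard errors are honest. With
  whole-site fires the covariate would be cluster-confounded with the
  trip intercept and no trip-level model could be calibrated against it.
* **Phase codes** (1 boom, 2 decline, 3 bust) are site-level terciles of
  eight-month rainfall over the camera window — phase enters the models
  as an observed covariate, and tying it to rainfall pulses gives it
  realistic serial structure.
* **Prey–predator simultaneity** is broken by time order, mirroring how
  the field streams decouple: predator photo counts in month *m* are
  generated from the rodent capture rate at the most recent preceding
  trip; rodent captures at trips inside month *m* are generated from
  that month's *observed* (simulated) photo rates; captures before the
  camera window use fixed baseline predator rates. Each node therefore
  sees in fitting exactly the covariate values used in generation — the
  property that makes 2-standard-error parameter recovery a meaningful
  calibration check, and which the suite verifies by rebuilding all
  analysis frames from the written tables and comparing them to the
  generator's own.
* **Ground truth** signs follow the fitted-network pattern (cover up
  with fire age and rain, seed up with cover, rodents up with seed and
  dingo but down with cat and fox, dasyurids down with mulgara,
  reptiles down with fire age); magnitudes were set once to produce
  realistic capture rates (a few animals per 100 trap-nights, a few
  photographs per night) and stable dynamics — in particular the
  rodents→dingo→rodents feedback is kept well below unit gain so the
  window simulation cannot run away. Trip-level random-intercept SDs
  (0.3–0.4 on the link scale) are exposed configuration, not asserted
  field values, since occasion-level variance is not published.

What the generator does *not* emulate: spatial rainfall correlation
between sites, animal movement, observation error in the vegetation
scores, irregular trip calendars, and any feedback from consumers to
vegetation. Passing tests therefore demonstrate that the estimator and
projection machinery are correct and calibrated for this model class —
not that the model class captures every feature of the field system.

## Scenario generation and propagation

`scenario_spec()` draws negative-binomial trajectories in the
mean/dispersion parameterization (variance `µ + µ²/size`): eight-month
rainfall with µ drifting 152 → 419 mm at `size = 1.57`, years since
wildfire 21 → 10 at `size = 3.34`, 12 time steps, 2000 draws per step.
The drift in µ is linear between the stated endpoints — only the
endpoints and the step count are given, so linearity is the default and
the per-step µ vector is overridable. `size` is held constant across
steps. Draws stay integer, as the distribution is.

`propagate()` re-enters each run's own draws node by node: cover from
(fire age, rainfall); that predicted cover into the seed equation with
rainfall; that predicted seed into the rodent equation with the
scenario's predator rates. Predictions are response-scale with random
effects at zero, so cover lies in [0, 100] %, seed in [0, 5] and rodent
rates (per 100 trap-nights) are positive by construction. Feeding each
run's own prediction forward (rather than the cross-run mean) lets
uncertainty compound; the reported s.e. is the SD across runs over √n.
Predator rates for the all-predators scenario are resampled with
replacement from the observed camera records and held constant across
steps — no predator-dynamics model is implied by the equations. The
rodent node runs 342 of the 2000 runs, reflecting its much shorter
predictor record.

One wording in the source method description is genuinely ambiguous: the
simulated drivers are said to be entered using the *standardized* path
coefficients. Standardized coefficients are range-normalized summaries
and cannot be multiplied onto millimetres or years, so the package
propagates the raw link-scale coefficients by default; a
`mode = "standardized"` variant (range-normalized inputs, effects summed
on the normalized response scale) is provided for comparison. The pooled
percentage change between scenarios is computed over all steps jointly —
per-step averaging windows were not specified.

## Problem sizes and runtime

The test suite fits the full nine-node SEM on a reduced design (5 sites,
18 trips, 12 camera months) for unit checks, and runs the calibration
harness at the full design scale — 9 sites, 25 trips, 24 camera months,
100 seeded replicates, every slope checked against its 2-SE interval —
in a few minutes on one core. Scenario and projection checks use the
full 2000-draw, 12-step trajectories.

## Known limitations

* Local estimation means no global goodness-of-fit or d-separation
  testing; the graph is fixed a priori and only its path strengths are
  estimated.
* Wald p-values at the camera nodes rest on n = 216 site-months; they
  are anti-conservative in the usual small-sample ways.
* The projection extrapolates: by design the rainfall trajectory drifts
  well beyond the fitted covariate range (a warning is raised), and the
  logit/log forms control the shape of that extrapolation.
* Percentage deviance explained compares marginal likelihoods and is not
  an R²; values across families are not directly comparable.
* The standardized-mode projection is a heuristic reading kept for
  comparison, not a recommended analysis path.
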