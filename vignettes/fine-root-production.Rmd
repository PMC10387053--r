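---
title: "Estimating fine root production from minirhizotron depth profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fine root production from minirhizotron depth profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootprod)
```

## The problem

Minirhizotrons — transparent tubes installed vertically in the soil,
photographed at fixed depths through repeated censuses — measure fine
root production (FRP) as the length of new roots appearing per window
area per month (m m⁻² mo⁻¹). The design this package emulates is a
tropical-forest campaign in the central Congo Basin: three ecosystem
types (*terra firme* forest, hardwood-dominated peat swamp,
palm-dominated peat swamp), 16 tubes per ecosystem, five photographed
depth windows (tops at 0, 6, 16, 36 and 71 cm, each spanning 2.5 cm)
and three one-month census intervals in different seasons — 720
observations in all.

Two statistical features dominate such data. First, roughly three
quarters of individual window measurements record *no* new roots: the
response is a non-negative continuous variable with a large point mass
at zero. Second, production declines steeply but smoothly with depth,
while the measurements cover only five discrete windows of a 1-m
profile, so a carbon budget per hectare needs a depth model, not just
the five sample means.

## The response model

For zero-inflated continuous rates we use the Tweedie
exponential-dispersion family with index parameter $p \in (1, 2)$,
mean $\mu$ and dispersion $\phi$, under which

$$Y = \sum_{i=1}^{N} G_i, \qquad N \sim \mathrm{Poisson}(\lambda),
\quad G_i \sim \mathrm{Gamma}(\alpha, \theta),$$

with $\lambda = \mu^{2-p}/(\phi(2-p))$,
$\alpha = (2-p)/(p-1)$ and $\theta = \phi(p-1)\mu^{p-1}$. The family
has $\mathrm{Var}(Y) = \phi\,\mu^{p}$ and an exact zero mass
$P(Y = 0) = e^{-\lambda}$, so zeros need no separate hurdle component.
`rtweedie()` samples by drawing $N$ and then a single
$\mathrm{Gamma}(N\alpha, \theta)$ variate; `dtweedie()` evaluates the
density at positive values by the Dunn–Smyth series expansion, with
the series truncated adaptively at a relative tail bound of $10^{-10}$
around its largest term.

`fit_frp()` fits the log-link regression of FRP on ecosystem, season,
depth (all categorical, sum-to-zero coded) and, by default, their
pairwise interactions. For each candidate index on a grid (default
1.1–1.9 in steps of 0.05; the emulated study never reports its fitted
power) the coefficients are obtained by iteratively reweighted least
squares — which for fixed $p$ is exact maximum likelihood regardless
of $\phi$ — and $\phi$ is then maximised against the series
log-likelihood. The reported fit is the grid point with the highest
profiled log-likelihood.

### Covariance and Type-III tests

Wald inference uses the inverse expected information
$\phi\,(X^{\top}WX)^{-1}$, $W = \mathrm{diag}(\mu^{2-p})$, evaluated
at the *maximum likelihood* dispersion. This is a deliberate choice:
with ~75% exact zeros the usual Pearson dispersion estimate is
strongly downward-biased (in our replicate simulations it averaged
14.8 when the generating value was 17.9), which inflates every Wald
chi-square; with the ML dispersion the nominal 5% test of a null
ecosystem effect rejects at ~7.5% and 95% Wald intervals on the depth
contrasts cover at ~94% over 200 replicates of the full design.

`type3_anova()` tests each term's coefficients jointly against zero in
the full model (Type-III convention under sum-to-zero contrasts),
giving chi-squares on 2, 2, 4, 4, 8 and 8 degrees of freedom for the
six terms of the full design. `marginal_means()` averages the linear
predictor with equal weight over the factors not requested and
back-transforms through the log link, with delta-method standard
errors; `pairwise_tukey()` compares all level pairs on the log scale
with studentised-range adjusted p-values. `aicc_compare()` ranks fits
by $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ and flags the
degenerate case $n \le k + 1$.

### Tube random intercepts

Measurements cluster within tubes. The emulated analysis found the
tube random intercept highly non-significant by AICc yet retained it
"in the interests of caution"; our default is the fixed-effects fit,
which is statistically equivalent for this design and exactly
specifiable. Setting `include_tube_intercept = TRUE` in
`model_spec()` delegates the mixed fit to **glmmTMB** (the standard
engine for Tweedie GLMMs, and what the original analysis used); the
fixed-effects path is authored here and cross-checked against glmmTMB
in the test suite.

## The synthetic-data generator

`generate_study()` draws one Tweedie deviate per design cell with mean
$\exp(x^{\top}\beta + b_{\mathrm{tube}})$. The calibrated default
(`default_generator_spec()`) encodes the study conditions:

* **Cell means.** The (ecosystem, depth) margin reproduces the
  published per-depth means exactly (e.g. palm 0–2.5 cm at 24.53
  m m⁻² mo⁻¹); seasons act multiplicatively with factors proportional
  to the published seasonal marginal means (3.9, 5.4, 6.2 m m⁻² mo⁻¹),
  normalised to average one. Because this structure is additive on the
  log scale in (ecosystem × depth) and season, the projection onto the
  sum-to-zero pairwise design is exact.
* **Index parameter** $p = 1.6$, mid-range of $(1, 2)$ — a default,
  not a published value, since the study reports no power estimate.
* **Dispersion** solved by `uniroot()` so the expected zero fraction
  across all 45 cells equals 0.75, the reported "three-quarters" of
  empty windows; this gives $\phi \approx 17$, i.e. extremely
  overdispersed data, which is what the published standard errors
  (±8.35 on a mean of 24.53 at $n = 48$) imply.
* **Tube intercepts** $b \sim N(-\sigma^2/2, \sigma^2)$ with
  $\sigma = 0.3$ by default, drawn once per tube and shared across
  seasons and depths; the $-\sigma^2/2$ centring keeps
  $E\,e^{b} = 1$ so cell sample means remain unbiased for the target
  means. The 0.3 magnitude is a judgement call (moderate between-tube
  heterogeneity); nothing in the published tables identifies it.
* All randomness flows from one integer seed through R's
  Mersenne–Twister generator; the generating truth is attached to the
  returned observation set.

What the generator does **not** emulate: spatial correlation between
paired tubes, root birth–death within a census interval, and any
tube-level variance differences between ecosystems. Passing tests on
synthetic data therefore demonstrate the estimation machinery under
the assumed model, not robustness to these departures.

## Depth extrapolation and the carbon chain

`fit_depth_loess()` fits locally weighted linear regression (tricube
weights) through the five per-depth means, and `predict_depth_grid()`
evaluates it at the midpoints of the forty 2.5-cm windows covering
0–100 cm, extending the boundary local fit below the deepest measured
window (72.25 cm) and clamping negative predictions to zero.

Numerical choices, made once and exposed as arguments:

* **Span 1, degree 1.** With five points, smaller spans leave local
  fits ill-posed (the fitter refuses spans where a local fit would see
  fewer than degree + 1 points and reports the minimum feasible span);
  degree 2 oscillates on sparse monotone profiles. The emulated study
  states neither value.
* **SE profile.** The five measured SEs are passed through the
  *identical* smoother, so section SEs at unmeasured depths are
  smoothed extrapolations of measured uncertainty — a reconstruction,
  consistent with the near-constant published deep-section SEs, but
  not a formal variance propagation through the LOESS fit.
* **Binning.** `bin_depth_profile()` averages the four windows of each
  10-cm section (conserving the grid average); the section *total* is
  recovered later by multiplying by the section depth inside the
  carbon conversion.

`section_carbon()` converts a section-mean rate $L$ (m m⁻² mo⁻¹) to
carbon flux:

$$C \;=\; \frac{L}{\mathrm{DOF}} \cdot \frac{1}{\mathrm{SRL}(z)}
\cdot d \cdot 12 \cdot 0.01 \cdot f_C
\quad \left[\mathrm{Mg\,C\,ha^{-1}\,yr^{-1}}\right]$$

with depth of field $\mathrm{DOF} = 2$ mm (the assumed visible soil
slab behind the tube wall; the window area cancels because $L$ is
already per m² of window), specific root length
$\mathrm{SRL} = 37.1 / 45.1 / 51.6$ m g⁻¹ for the 0–10 / 10–20 /
20–100 cm bands, section depth $d = 0.1$ m, twelve months per year,
0.01 to convert g m⁻² to Mg ha⁻¹, and carbon fraction $f_C = 0.474$.
With the defaults the whole chain collapses to
$C = 2.844\,L/\mathrm{SRL}$, an identity the tests verify against the
stepwise computation at $10^{-12}$ relative tolerance. Monthly
seasonal estimates are averaged *before* the ×12 annualisation — the
only reading of "multiply the monthly estimate by twelve" that yields
one annual number from three measured months. Total SE per profile is
the root-sum-of-squares of the ten section SEs.

The depth-weighted 0–75 cm profile mean (`depth_weighted_mean()`)
weights each window by the span of the midpoint partition it
represents — boundaries at the surface, halfway between adjacent
window midpoints, and at 75 cm, giving widths (4.25, 8, 15, 27.5,
20.25) cm. This weighting is itself a reconstruction: it reproduces
the published 4.1 (terra firme) exactly at one decimal, gives 4.63
against a published 4.7 for the hardwood site and 6.49 against 6.6
for the palm site. The residual gaps are consistent with the
published inputs being printed at two decimals and are carried,
documented, in the reproduction report rather than hidden.

## Reproduction report and pipeline

`reproduce_reference()` recomputes, by pure arithmetic on the packaged
reference tables (no fitting, no randomness, bit-identical re-runs):
the grand per-depth means (21.2 → 0.7 m m⁻² mo⁻¹), the percentage of
surface FRP found at 16–18.5 cm (1.1% / 32.8% / 35.7%) and 71–73.5 cm
(8.3% / 1.6% / 1.2%), the 0–30 cm carbon sums (1.1 / 1.5 / 2.4
Mg C ha⁻¹ yr⁻¹), profile totals, propagated total SEs (0.13 / 0.54 /
0.26) and the depth-weighted means. Each check records the band it is
compared at: exact printed-decimal agreement where the arithmetic is
closed, a wider documented band where the published inputs are
themselves rounded.

`run_pipeline()` chains simulate → validate → fit → marginal means
(per ecosystem × depth, averaged over seasons on the link scale) →
LOESS profile → binning → carbon table, writes CSV/JSON artifacts,
and is byte-reproducible given the seed. A thin command-line wrapper
with subcommands (`simulate`, `fit`, `profile`, `carbon`,
`reproduce`, `run`) ships in `inst/scripts/frp_pipeline.R`.

## Simulation design and problem sizes

The replicate simulations in the test suite run 200 replicates of the
full 720-observation design. The generating truth for the recovery,
power and size checks is additive — the grand per-depth means shared
by all ecosystems (a *null* ecosystem effect), seasonal multipliers,
dispersion re-solved for the 0.75 zero fraction, no tube effects — and
the fitted recovery model is that generating model. Two choices there
deserve a note:

* *Why not fit the full interaction model in the recovery check?*
  Under $\phi \approx 18$ and 75% zeros, the saturated 29-parameter
  fit estimates deep-layer cell means from a handful of positive
  observations; the log of such an estimate carries a finite-sample
  Jensen-type bias of order $-\tfrac{1}{2}\phi\mu^{p-2}/n_{cell}$,
  which we measured at ~+0.15 on the shallow depth contrasts (and
  ~0.86 Wald coverage) *even when the true dispersion is supplied* —
  an intrinsic property of ML at this design size, not an
  implementation defect, and a practical caution for interpreting
  saturated Tweedie fits to data this sparse.
* *Why no tube effects in the size simulation?* Tubes are nested in
  ecosystems; unmodelled tube-level clustering would make any
  fixed-effects ecosystem test anticonservative for reasons unrelated
  to the test statistic itself. The size check therefore generates
  under the fitted model's own assumptions. For clustered data the
  random-intercept variant exists, and its glmmTMB engine is exercised
  separately.

The Tweedie sampler is checked against its closed-form mean, variance
and zero mass at $n = 10^5$ within three Monte-Carlo standard errors;
the LOESS path against an independent closed-form tricube
weighted-least-squares solve; the series density against an
independent evaluation (`mgcv::ldTweedie`) and against numerical
integration of the continuous part plus the zero atom.

## Known limitations

* The published per-depth tables are the only public data; model-level
  outputs of the original analysis (its ANOVA chi-squares) depend on
  the unreleased raw observations and are deliberately not
  reproduction targets — the model path is validated on synthetic data
  instead.
* The LOESS span/degree and SE-extrapolation rule of the original
  analysis are unstated; ours are documented reconstructions, isolated
  behind arguments so they can be swapped.
* Depth-of-field and SRL values carry large systematic uncertainty
  (halving the depth of field doubles every carbon flux — the tests
  check exactly this sensitivity direction); the propagated SEs are
  sampling uncertainty only.
* One orientation per depth is assumed, matching the emulated
  protocol; the data model stores one value per (ecosystem, tube,
  season, depth) key and does not average multiple orientations.
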