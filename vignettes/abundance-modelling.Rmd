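---
title: "Modelling Arctic prokaryotic and viral abundances with small regression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Arctic prokaryotic and viral abundances with small regression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcticann)
```

## The problem

Flow cytometry resolves Arctic seawater microbes into four populations:
high and low nucleic-acid prokaryotes (HNA, LNA; 10^5 cells mL^-1) and
high- and low-fluorescence viruses (V1, V2; 10^6 particles mL^-1). The
question this package addresses is empirical model development: which of
five easily measured covariates — chlorophyll-a (a proxy for the supply of
phytoplankton-derived dissolved organic matter), water temperature,
salinity, depth, and day length — best predict each population's abundance,
and what do the fitted response surfaces imply about the underlying
ecology?

The modelling protocol is deliberately simple and fully automated:

1. **Data preparation.** A seasonal fixed-station time series (n = 156;
   eight depths between 3 and 220 m, 21 dates from early November to early
   August) is split 80/20 into training and test sets; all covariates and
   responses are standardized to zero mean and unit variance. Day length
   (sunrise to sunset, hours) is computed from date and coordinates with a
   low-precision solar-position algorithm (zenith 90.833°, so refraction
   and the solar radius are included); above the Arctic Circle it clips to
   exactly 24 h in midsummer and 0 h in midwinter.
2. **Candidate networks.** Each covariate subset of size 1–3 is crossed
   with two network families — feed-forward (one sigmoid hidden layer, bias
   terms feeding the hidden and output layers) and radial-basis-function
   (Gaussian bumps, bias only in the output layer) — and hidden-unit counts
   2–15: 700 architectures per response.
3. **Training.** Levenberg–Marquardt least squares for exactly 100
   iterations, recording the parameter vector and train/test RMSE at every
   iteration. The test set never influences the update; it only indexes
   the record. The network is *reconstituted* at the iteration minimizing
   the combined (train + test) RMSE — early stopping by record lookup, with
   ties broken toward the earlier iteration.
4. **Random restarts.** Because the loss surface is multimodal, each
   architecture is trained from many random initializations (100 in a first
   screening phase, 1000 for the shortlisted architectures in a second
   phase), keeping the restart with the smallest combined RMSE. Nonlinear
   parameters are initialized inside the data range (sigmoid inflection
   surfaces anchored at points in the data box; RBF centers uniform in the
   box, widths 0.2–2 times the mean data spread); linear parameters are
   Uniform(−1, 1).
5. **Evaluation and selection.** An independent summer survey (n = 37,
   depths ≤ 80 m) supplies out-of-distribution evaluation data. Observed
   abundances are regressed on model predictions; among candidates with
   evaluation r² > 0.5, the model whose slope is closest to 1 wins (ties:
   smaller combined RMSE). If nothing passes the gate the result is an
   explicit "no admissible model". Totals (all prokaryotes, all viruses)
   are obtained by summing the component model predictions, never by a
   separate model.
6. **Baseline.** Bidirectional stepwise multiple linear regression
   (p-to-enter = p-to-remove = 0.05, partial-F criterion) on
   log-transformed data (natural log of depth, chlorophyll and abundances;
   temperature, salinity and day length untransformed) fitted to the
   seasonal data and evaluated on the survey.

`ann_fit()` is the package's central function; `run_pipeline()` executes
steps 1–6 from one master seed.

## The synthetic study conditions

The original field data are not publicly deposited, so the package ships a
synthetic generator that emulates the two campaigns down to their printed
summary moments. Every stochastic column (temperature, salinity,
chlorophyll, four abundances) is drawn from a smooth structural model plus
noise and then *moment-calibrated*: strictly positive columns by a
power-law map `y = s·x^b` (an affine map on the log scale, rank-preserving;
`b` solved so the coefficient of variation matches, `s` fixing the mean),
other columns affinely. Sum columns are recomputed afterwards so
`prokaryotes = HNA + LNA` and `viruses = V1 + V2` hold exactly.

The latent response surfaces define the synthetic truth:

* **HNA** — an additive mix (weights 0.4/0.6) of a Gaussian temperature
  bump centred at −0.8 °C (width 1.3 °C) and a chlorophyll power term
  `(chl/0.08)^0.85`. The bump keeps the surface unimodal in temperature
  with its maximum in the −1.3…−0.3 °C band at any chlorophyll level.
* **LNA** — a saturating logistic increase in temperature (midpoint
  −0.5 °C, scale 0.9 °C) times `(chl/0.08)^0.3`.
* **V1** — `(chl/0.08)^0.7` times a day-length factor whose exponent decays
  with depth (e-folding 60 m; light matters only near the surface), times
  an exponential depth decline (e-folding 180 m).
* **V2** — an additive mix of an exponential depth decline (weight 0.15,
  e-folding 140 m), a depth-attenuated chlorophyll term (weight 0.55,
  `(chl/0.08)^0.6 · exp(−z/160)`), and a weak day-length term (0.15). The
  surface is strictly decreasing in depth at every chlorophyll level.

Abundances are `surface × exp(ε)` with ε Gaussian (SD 0.35 on the log
scale); half of the noise variance is a water-sample-level effect shared by
all four populations, which propagates realistic covariance into the summed
totals. Effect sizes were chosen so the surface log-SD across each campaign
(≈ 0.4–0.7) comfortably exceeds the noise — without that margin a screen at
n = 156/37 could not identify predictors at all, and the generator would not
exercise the downstream machinery it exists to test.

Two deliberate features mirror the published campaign structure:

* **Seasonal salinity is a low-noise proxy of the warming/runoff signal,
  while survey salinity is governed by distance to the river plume.** A
  stepwise linear model fitted to the seasonal data therefore tends to
  recruit salinity and transfers poorly to the survey — the behaviour the
  original stepwise baselines showed — whereas the network candidates, which
  are offered compact covariate subsets, are unaffected.
* **The survey is warmer, fresher, shallower, better lit and more
  productive than the time series** (every column separates at p ≤ 0.05
  with the published direction), so evaluation is genuinely
  out-of-distribution.

### What the generator does not emulate

Only the printed moments and qualitative gradients constrain the fields:
there is no ice cover, no nutrient or discharge forcing, no advection, and
no measurement-error model beyond the lognormal noise. The printed *minima*
of the survey abundance columns are single-sample outliers several noise
SDs below their means (V1's printed minimum is 3% of its mean); a Gaussian
log-noise model cannot produce them at n = 37, so generated survey minima
sit above the printed ones. Passing tests therefore demonstrate that the
method pipeline behaves correctly under controlled, recoverable conditions
— not that real Arctic data would yield these particular models.

## Numerical choices

* **Levenberg–Marquardt.** Damping starts at 1e-2, is divided by 10 after
  an accepted step (training SSE decreased) and multiplied by 10 otherwise,
  with up to 10 inner attempts per outer iteration and bounds 1e-12…1e12.
  "100 iterations" counts outer iterations regardless of inner retries; an
  iteration whose attempts all fail leaves the parameters unchanged. A
  singular system at every damping level flags the run as failed, and such
  restarts are excluded from screens.
* **Scaling.** The scaler is fitted on the full seasonal table (train and
  test pooled), and the same scaler transforms the survey. Responses are
  scaled for training and predictions inverse-transformed, never clipped at
  zero: negative predictions are a meaningful extrapolation diagnostic.
* **Moment calibration.** The exponent `b` is found by root-finding on the
  coefficient of variation (tolerance near machine precision), so calibrated
  means and SDs match their targets to ~1e-9. A constant column with a
  nonzero target SD is an error.
* **Splitting.** The 80/20 split is stratified by sampling date
  (largest-remainder allocation, seeded), so every part of the season
  appears in both subsets; the protocol source does not state how the
  original split was made.
* **Seeds.** All randomness derives from one master seed through a
  documented hash: each (architecture, restart index) pair maps to a child
  seed independent of phase, so the 1000-restart phase reuses and extends
  the 100-restart phase's stream, and a deeper screen can never be worse.
* **Simulation grids** default to 50 points per continuous axis; grid nodes
  outside the training range, or in empty bins of the seasonal support
  histogram, are flagged as extrapolation.

## Reduced-scale defaults

The full protocol (700 architectures × 100/1000 restarts × four responses)
is hours of compute; it is available as the `"full"` preset of
`pipeline_config()`. The `"ci"` preset used by the test suite reduces the
screen to two covariate combinations per response (the generating set plus
a disjoint decoy), hidden counts {2, 4}, both families, 5 first-phase
restarts, re-screening of every architecture with 25 second-phase restarts,
and 30 training iterations. At that scale a full pipeline takes tens of
seconds; across repeated master seeds the selected HNA model includes
temperature, the selected V2 model includes depth or chlorophyll, and the
selected networks beat the stepwise baseline's survey r² — the qualitative
findings the protocol is designed to produce.

## Known limitations

* The evaluation survey extrapolates far beyond the training ranges
  (temperature to ≈ 8.5 °C against a training maximum of 2.8 °C), so
  survey r² values are volatile across seeds; occasional "no admissible
  model" outcomes for LNA are expected at the reduced scale.
* The printed survey abundance minima are unreachable under the lognormal
  noise model (above).
* `smlr()` uses coefficient t-tests (equivalent to single-step partial F);
  exotic designs with aliased predictors are not handled.
* Day length is astronomical daylight; no twilight or ice-cover correction.
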