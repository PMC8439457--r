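---
title: "Modelling anthropogenic microparticle concentrations in lakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anthropogenic microparticle concentrations in lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakemp)
```

## The problem

Microplastics and anthropogenic fibres (together, *microparticles*,
roughly 300 µm–5 mm) accumulate in lake surface waters, but the landscape
and in-lake features that predict their concentrations are poorly
quantified.  `lakemp` implements a complete, testable analysis chain for
this question:

1. **Harmonisation of net-tow records** (`towdb`): converting areal to
   volumetric concentrations, deriving filtered volumes from net geometry,
   attaching per-tow detection limits, and scoring methodological
   reliability.
2. **A censored log-normal mixed model** for a global tow database:
   concentrations vary by habitat (lake, river, marine/estuarine) and mesh
   size, studies contribute random intercepts, and recorded zeros are
   treated as censored below a detection limit rather than as true
   absences.
3. **A Bayesian Poisson hurdle regression** for a continental lake survey:
   an intercept-only Bernoulli detection part and a zero-truncated Poisson
   count part whose log mean is a linear combination of six standardised
   predictors — estimated plastic mass input (cube-root), wastewater
   treatment load (population equivalents), forest and urban catchment
   cover, dark-bottle respiration (cube-root), and the CDOM spectral slope
   (log).
4. **Catchment delineation** (`catchment`): priority-flood depression
   filling, D8 flow direction and accumulation, pour-point selection by
   maximum in-lake accumulation, and upstream watershed tracing, plus land
   cover and wastewater-load summaries.
5. **Plastic-emission accounting** (`emissions`): mismanaged plastic waste
   (MPW) generation coupled with monthly runoff and integrated over the
   lake's water retention time.
6. **Assay reductions** (`limnoassays`) and **FTIR processing**
   (`spectra`).
7. **A sampling-volume sensitivity simulation** (`bias_sim`): how strongly
   sampling volumes must vary and correlate with observed concentrations
   before model conclusions change.

## The two models

### Censored log-normal mixed model

For tow $i$ in study $s(i)$ and habitat $h(i)$ with standardised mesh size
$m_i$ and detection limit $L_i$:

$$\log y_i \sim \mathcal N(\mu_i, \sigma^2), \qquad
\mu_i = \alpha_{h(i)} + \beta_{\text{mesh}} m_i + u_{s(i)}, \qquad
u_s \sim \mathcal N(0, \sigma_{\text{study}}^2).$$

A recorded zero contributes
$\Pr(y_i < L_i) = \Phi\!\big((\log L_i - \mu_i)/\sigma\big)$: microparticles
are ubiquitous, so zeros mean "below what this tow could detect", and each
record's limit is one particle per filtered volume (the smallest observable
nonzero concentration).  A value exactly at its detection limit is treated
as observed, not censored.

Internally the sampler works on per-study means
$v_s = \alpha_{h(s)} + \beta_{\text{mesh}}\bar m_s + u_s$ (a centred
parameterisation): the tow likelihood then involves only $v_s$ and
within-study mesh deviations, which decorrelates the coordinate-wise
updates and gives near-independent draws.

### Poisson hurdle model

For lake $j$ with count $k_j$ and standardised predictor row $x_j$:

$$k_j = 0 \text{ with probability } 1-\pi, \qquad
k_j \mid k_j > 0 \sim \text{ZTPois}(\lambda_j), \qquad
\log \lambda_j = \beta_0 + x_j^\top \beta.$$

The detection part is intercept-only: one probability of detecting
microparticles across all samples (a covariate-bearing detection part is a
natural extension but is deliberately not the default).  Tow volume is
constant across lakes (7.1 m³), so no offset term is needed; it enters only
when reporting concentrations $k/V$.  Marginal-effect curves report
$\pi\,\lambda/(1-e^{-\lambda})/V$ along one standardised predictor with the
others at 0; the detection probability is marginalised in (multiplied) by
default, with conditioning available via a flag.

### Priors, sampling and diagnostics

Weakly informative defaults: $\mathcal N(0, 2.5)$ on standardised-scale
coefficients, half-$\mathcal N(0, 2.5)$ on standard deviations,
$\mathrm{Beta}(1,1)$ on $\pi$; all overridable.  Sampling uses a built-in
slice-within-Gibbs sampler (stepping-out and shrinkage, per-coordinate
width adaptation during warmup).  No external HMC engine is required; any
backend passing the gates is interchangeable.  Fits are *flagged*, never
silently accepted, when split-$\widehat R > 1.01$ or rank-based
$\mathrm{ESS} < 800$.  Model comparison uses Pareto-smoothed
importance-sampling leave-one-out cross-validation with per-observation
$\hat k$ diagnostics (flagged above 0.7), and fit is summarised by a
Bayesian $R^2$: per draw, the fitted-value variance over itself plus the
mean model-implied residual variance.

## What the synthetic world encodes — and what a green test means

The generator defaults are fixed once, from the surveyed world, and are
not tuning knobs:

* `lake_sim_config()`: 67 lakes, tow volume 7.1 m³, detection probability
  56/67 (11 of 67 lakes had zero counts), intercept $\log 2$ so the median
  concentration sits near 0.28 particles m⁻³ (median count ≈ 2 in
  7.1 m³), and true standardised coefficients at the midpoints of the
  reported 95% effect intervals: 0.29 (plastic input), 0.225 (wastewater
  load), −0.205 (forest), −0.01 (urban), −0.32 (respiration), 0.01
  (spectral slope).
* Raw predictors are drawn from skewed families chosen to motivate the
  analysis transforms — lognormal plastic input and spectral slope,
  lognormal wastewater load with a 25% point mass at zero (catchments
  without treatment works), Beta land-cover proportions, half-normal
  respiration — then cube-root/log-transformed and standardised exactly as
  in the analysis.
* `towdb_sim_config()`: ~2,160 tows across 90 studies (the published
  database has >2,100), habitat log-means ordered river > marine ≈ lake
  with contrasts of the reported order, study SD 1.0 and residual SD 0.8
  on the log scale, mesh sizes uniform on the observed 45–780 µm window,
  volumes log-uniform on 1–1,000 m³.
* The toy landscape is a deterministic raster world: terrain sloping to a
  single bottom-edge outlet, a teardrop lake with a raised shoreline and a
  single spill channel (so the lake provably lies inside the watershed of
  its own pour point), coded land cover, population concentrated on urban
  cells, a seasonal 12-month runoff series and two treatment plants.

A green test therefore establishes that the estimators recover the worlds
they assume — correct likelihoods, correct routing, correct calibration —
not that real lakes obey these distributions.  Real survey data bring
spatial correlation, measurement error in predictors, and non-Poisson
overdispersion that the synthetic world deliberately omits.

## Numerical and design choices

* **Depression handling**: priority-flood *filling* to exact spill level
  (GIS workflows often *breach* depressions instead; on any DEM whose
  drainage pattern matters here the two agree).  Flats left by filling are resolved inside
  `d8_flow_direction()` by a breadth-first sweep from already-draining
  cells, i.e., flat cells drain along shortest paths towards lower ground.
* **D8 conventions**: neighbour order E, SE, S, SW, W, NW, N, NE with
  power-of-two codes; steepest descent is drop over distance with
  $\sqrt 2$ diagonals; ties go to the first neighbour in the ordering;
  grid indices are (row, col) with row 1 the north edge; rasters use the
  ESRI ASCII format with a lower-left origin and half-open
  $[x, x+\text{cell})$ point membership.
* **Pour points**: the maximum-accumulation cell within the lake mask,
  optionally dilated by one pixel (`buffer_px = 1`) when the outflow area
  is flat.  The flatness criterion itself is left to the user — field
  workflows apply the buffer case-by-case without stating one.
* **Emission formula**: monthly emission is
  $a\big(\sum_i \mathrm{MPW}_i\, A_i\, g(R_i)\, d\big)^b$ with a linear
  runoff coupling by default and $a = b = 1$.  Published calibrations of
  such emission formulas are region- and dataset-specific, so the
  coefficients are parameters, not constants.  Retention-time
  integration weights a fractional oldest month proportionally.
* **Standardisation** uses the sample ($n-1$) SD and keeps the constants
  for back-transformation.  Respiration units (per day) cancel under
  standardisation, so the model is invariant to that choice.
* **FTIR baseline**: the "15% adaptive baseline" of common spectroscopy
  software is proprietary; it is approximated by a rolling-minimum
  baseline (window 15% of the spectral span) smoothed by a rolling mean,
  then peak-normalised to 1.  Matching uses Pearson correlation over
  700–1,850 cm⁻¹ after linear resampling to a 4 cm⁻¹ grid, accepting
  matches at $r \ge 0.90$.
* **Volume-bias simulation**: volumes are marginally
  $\mathcal N(\mu, \sigma^2)$, correlated with the zero-inflated, skewed
  concentration vector through a Gaussian copula on rank-transformed
  concentrations.  The copula attenuates the raw-scale Pearson
  correlation, so the loading on the normal scores is inflated by the
  score/raw correlation to hit the target $r$; unattainable targets fall
  back to the maximum with a warning.  Both hurdle components are refit in
  each replicate, and per-replicate seeds derive from the (σ, r,
  replicate) index so results are independent of execution order.
* **Mesh size** enters the global model standardised on the raw scale
  (a log-scale variant is a one-line change upstream of
  `cens_lnm_data()`); detection limits act through the censoring bound,
  never as a covariate.

## Known limitations

* The slice sampler is single-threaded and coordinate-wise; posteriors
  with strong unmodelled correlations (e.g., a centred hierarchical
  parameterisation) would mix slowly.  The shipped parameterisations avoid
  the known pathologies.
* The emission module does not route water between multiple lakes and the
  toy landscape has exactly one lake.
* The bundled FTIR library contains four *synthetic* band patterns; it
  stands in for, and must not be confused with, measured reference
  libraries.
* Reduced MCMC settings are used throughout the test suite to stay inside
  CI time budgets; they pass looser Monte Carlo bands than a production
  run (4 chains, ≥1,000 post-warmup draws) would.
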