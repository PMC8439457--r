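# lakemp

Tools for analysing anthropogenic microparticle (microplastic and
anthropogenic fibre) concentrations in lake surface waters, and for
relating them to catchment and in-lake drivers.

The package is aimed at freshwater scientists who have net-tow counts and
want a defensible statistical treatment of three recurring problems:

1. **Zeros are not absences.** A tow that filters volume *V* cannot see
   concentrations below 1/*V*. The global-database model is a censored
   log-normal mixed model: for tow *i* in habitat *h(i)* and study *s(i)*,

   log *y*ᵢ ~ N(α₍ₕ₎ + β_mesh·meshᵢ + u₍ₛ₎, σ²), u_s ~ N(0, σ_study²),

   with recorded zeros contributing Φ((log *L*ᵢ − μᵢ)/σ), the probability
   of lying below the tow's detection limit *L*ᵢ.

2. **Lake counts are zero-inflated and small.** The per-lake survey model
   is a Bayesian Poisson hurdle: detection with probability π, and
   positive counts from a zero-truncated Poisson whose log mean is a
   linear combination of six standardised predictors (cube-root plastic
   mass input, wastewater load in population equivalents, forest and urban
   catchment cover, cube-root dark respiration, log CDOM spectral slope).

3. **Predictors must be built from rasters and raw assays.** The package
   delineates lake catchments from a DEM (priority-flood filling, D8 flow
   direction/accumulation, pour point at the maximum in-lake accumulation,
   upstream watershed tracing), sums land cover and wastewater loads,
   couples mismanaged-plastic-waste grids with monthly runoff integrated
   over the lake retention time, reduces O₂ incubations to respiration and
   productivity rates, fits the 275–295 nm CDOM spectral slope, and
   preprocesses/matches ATR-FTIR spectra (Savitzky–Golay, rolling-minimum
   baseline, Pearson matching at r ≥ 0.90 over 700–1,850 cm⁻¹).

Inference runs on a built-in slice-within-Gibbs sampler with split-R̂ and
rank-based ESS gates (≤ 1.01 and ≥ 800), PSIS-LOO cross-validation and
Bayesian R². A synthetic-data module generates every input — tow
databases, lake surveys, toy raster landscapes, CDOM/FTIR spectra — so the
whole pipeline runs and is tested without any external download. A
sensitivity module re-runs the hurdle model with sampling volumes
correlated to observed concentrations to ask how severe volume bias must
be before conclusions change.

## A worked example

```r
library(lakemp)

# deterministic survey facts
compute_sample_volume(0.300, 100, signif_digits = 2)  # -> 7100 (litres)
reliability_score(reliability_checklist(TRUE, TRUE, TRUE, TRUE,
                                        TRUE, TRUE, TRUE))  # -> 11

# a synthetic 67-lake survey calibrated to the surveyed world
survey <- gen_lake_survey(lake_sim_config(seed = 42))
sum(survey$count == 0)                    # -> 5 zero-count lakes
median(survey$concentration_per_m3)       # -> 0.2816901 particles m^-3

# fit the hurdle model and summarise an effect
d   <- hurdle_data(survey$count, attr(survey, "X"))
fit <- fit_hurdle(d, mcmc = list(chains = 4, iter = 1000, warmup = 500,
                                 seed = 7))
summary(fit)[summary(fit)$param == "beta[respiration]", ]
#               param       mean        sd      q2.5     q97.5 rhat  ess
# 7 beta[respiration] -0.3584299 0.1044526 -0.560701 -0.157728    1 2563

bayes_r2(fit)$mean                        # -> 0.3476987
marginal_effect(fit, "plastic_input")$endpoint_ratio$mean  # -> 1.591794
```

The respiration coefficient is negative with a 95% credible interval
excluding zero: lakes whose water consumed oxygen faster in dark
incubations carry fewer microparticles, the generator's truth (−0.32)
well inside the interval. The endpoint ratio is the factor by which
expected concentration changes across the observed range of a predictor
with all others held at their means.

A toy landscape exercises the GIS chain:

```r
land <- gen_toy_landscape(21, seed = 3)
cs <- catchment_summary(land$dem, land$lake_mask, land$landcover,
                        land$wwtw_points)
cs$area_km2      # catchment area draining to the lake pour point
cs$forest_prop   # proportion of catchment pixels under forest
cs$wwtw_load_pe  # wastewater load (population equivalents) inside it
```

## Command line

A thin CLI wraps the main stages (configs are JSON):

```sh
lakemp simulate --what lakes --seed 1 --out sim/
lakemp fit-lakes --survey sim/lake_survey.tsv --out fit
lakemp catchment --dem dem.asc --lake lake.asc --landcover lc.asc --out s.json
lakemp bias-sim --survey sim/lake_survey.tsv --out grid.csv
```

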