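---
title: "Pedestrian energy budgets and urban cooling scenarios: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedestrian energy budgets and urban cooling scenarios: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatbudget)
```

## The problem

During extreme heat events (EHEs), the risk of heat illness is not uniform
across a city: neighbourhoods with sparse tree canopy and extensive dark
paving expose pedestrians to far larger radiant loads than leafy ones, and
emergency medical response (EMR) call counts track that exposure. This
package implements a complete, seeded, self-contained version of that
analysis chain: a steady-state human energy-budget model of the COMFA
family driven by hourly weather; land-cover extraction that turns
classified rasters or greyscale plan images into per-tract class
proportions; proportion-weighted tract energy budgets with "cooling"
design scenarios; the study-style statistical battery; and synthetic
generators for every input so the whole chain runs and is tested without
any external data.

## The energy-budget model

The budget of a standing/walking person (W m^-2^) is the five-term sum

$$\mathrm{EB} = M + R - H - L - E$$

with metabolic heat reaching the body surface ($M$), absorbed short- plus
long-wave radiation ($R$), sensible (convective) loss ($H$), emitted
long-wave ($L$), and evaporative loss ($E$). Positive budgets are net heat
gain; the thermally neutral range is conventionally bounded near
+150 W m^-2^, with roughly 150-200 "warm" and above 200 "hot". The
five terms are composed exactly — `energy_budget()` returns components
whose sum is the reported `EB` to machine precision, and the test suite
asserts this on randomized inputs.

The reference pedestrian (`person_params()`) walks slowly (metabolic
activity 192 W m^-2^) in hot-weather clothing (static clothing resistance
50 s m^-1^), with skin at 33 °C, core at 37 °C, body albedo 0.37 and
emissivity 0.95, modelled radiatively as a vertical cylinder (0.17 m
diameter, 1.7 m tall).

Station wind at 10 m is converted to the 1.5 m walker height with a
logarithmic profile over short grass,
$u_{1.5} = u_{10}\,\ln(1.5/(0.13\cdot0.8))/6.65 \approx 0.4013\,u_{10}$,
and sky observations are reclassified to three levels carrying bulk
shortwave transmittances 0.75 (sunny), 0.40 (partly cloudy) and 0.25
(cloudy).

### Flux sub-models and their constants

Only the budget summation, the wind conversion and the parameter values
above are fixed by the study design; the flux sub-models themselves are a
concrete default formulation assembled from standard biometeorological
forms, with **every constant in one configuration block**
(`comfa_config()`) so the calibration is transparent and overridable:

* **Solar geometry.** Zenith angle from the standard fractional-year
  declination/equation-of-time expansions (`solar_zenith()`), on a fixed
  daylight-savings clock (UTC−4) at the Toronto station coordinates
  (+43.6667°, −79.3774°).
* **Shortwave.** Beam normal irradiance $S_\perp = S_0\,\tau^{1/\cos Z}$;
  diffuse $= d_f (1-\tau^{1/\cos Z}) S_0 \cos Z$; cylinder beam
  interception $\sin Z/\pi + (d/4h)\cos Z$; person absorbs
  $(1-\alpha_p)[\text{beam} + 0.5\,\mathrm{svf}\cdot\text{diffuse} +
  0.5\,\alpha_{grd} K_{ground}]$. A deciduous canopy overhead multiplies
  the beam by its transmissivity (0.45, the visible-spectrum transmission
  of trees in leaf) and shades the ground.
* **Longwave.** Sky emission with effective emissivity
  $\epsilon_{sky} = b + c\,T_a + 0.2\,f_{cloud}$ (capped at 1); sunlit
  ground warms as $T_{sf} = T_a + k(1-\alpha_{grd})K_{global}$ and emits
  $\epsilon_{grd}\sigma T_{sf}^4$; vertical surfaces filling the
  $(1-\mathrm{svf})$ view factor radiate at air temperature (no wall
  model is specified by the study). The person emits at the clothing
  surface temperature, a resistive interpolation
  $(T_{skin} r_a + T_a r_c)/(r_a + r_c)$.
* **Sensible.** $H = \rho c_p (T_{core}-T_a)/(r_t + r_c + r_a)$ with
  aerodynamic resistance $r_a = k_a\sqrt{d/u_{1.5}}$ capped at
  500 s m^-1^ in calm air. $H$ changes sign exactly at core temperature:
  convective *gain* above 37 °C.
* **Evaporative.** $E = (\rho c_p/\gamma)\, w\,
  (e_s(T_{skin}) - e_{air})/r_v$ with Tetens saturation pressures,
  vapour resistance proportional to the heat-resistance pathway, floored
  at zero (no condensation gain — appropriate for the heat-event regime).
* **Metabolic.** $M = M_a - E_{resp} - C_{resp}$ with
  $E_{resp} = 0.0023\,M_a(44 - e_{air}[\mathrm{hPa}])$ and
  $C_{resp} = 0.0014\,M_a(34 - T_a)$, each floored at zero so
  $0 < M \le M_a$ even in very hot, humid air.

### Calibration

The published analysis used an interactive spreadsheet implementation of
the COMFA model whose internal sub-equations are not restated in print;
what is printed are city-wide outcomes: the heat-event elevation of the
baseline budget (+70 to 80 W m^-2^), existing-design heat-event tract
budgets of 190-195 W m^-2^ falling to 165-170 W m^-2^ under the cooling
designs, and within-tract reductions of −20 ± 2 and −30 ± 3 W m^-2^. The
free constants of the configuration block were therefore calibrated, once,
by least squares against those printed ranges under the study conditions
(the generator defaults below), and the calibrated values are the package
defaults:

| constant | meaning | value |
|---|---|---|
| `diffuse_frac` | diffuse irradiance fraction | 0.376 |
| `r_aero_coef` | aerodynamic resistance coefficient | 350 |
| `r_tissue` | vasodilated tissue resistance | 26.3 s m^-1^ |
| `vapor_res_factor` | vapour/heat resistance ratio | 2.209 |
| `sky_emis_base`, `sky_emis_ta` | effective clear-sky emissivity | 0.425, 0 |
| `surf_heat_veg` | vegetated surface heating | 0.0279 °C per W m^-2^ |
| `surf_heat_paved` | paved/bare surface heating | 0.0414 °C per W m^-2^ |

Two of these deserve comment. The vegetated/paved split of the surface
heating coefficient encodes transpirational cooling of turf relative to
asphalt — with a single coefficient, sunlit grass would be modelled as hot
as pavement, which inverts the grass/asphalt contrast the design scenarios
rely on. The low effective sky emissivity compensates the deliberately
simple radiation geometry (hemispheric view factors of one half, walls at
air temperature); it is an *effective* parameter of this closed model, not
an atmospheric measurement. Because the calibration touches only the
magnitude constants, all structural properties — additivity, sign
conventions, monotonicities, the exact 0.45 canopy attenuation — are
independent of it, and the test suite checks them against separately coded
straight-line oracles at 10^-9^ relative tolerance.

## From land cover to tract budgets

The land-cover layer is an eight-class, 0.6 m classified raster (Tree
Canopy, Grass/Shrub, Bare Earth, Water, Building, Road, Other Paved,
Agriculture). Pixel counts per tract become areas
(`counts_to_areas()`; 10,000 pixels at 0.6 m = 0.36 ha), are checked
against the tract polygon area (`area_consistency_check()`), and reduce to
the five classes of interest (`proportions_of_interest()`): Grass/Shrub
merges with Agriculture; Water and Building are dropped (buildings are
outside the energy-budget calculation) and the rest renormalised.
Greyscale master-plan images with one grey level per class are counted by
`classify_grey_plan()`, strict by default because plan levels are exact;
`render_grey_plan()` is its inverse, and round-trip exactness is tested.

Each class of interest is one homogeneous micro-environment
(`site_for_class()`): canopy sits under trees (sky-view 0.2, shaded
ground); grass is the reference turf (albedo 0.25); bare earth 0.30;
roads and other paving are asphalt (albedo 0.10, emissivity 0.90). The
tract's predicted energy budget (pEB, `tract_peb()`) is the
proportion-weighted mixture of the class budgets, hour by hour, averaged
over the 11h00-18h00 window — an exposure-weighting interpretation that
makes every pEB a convex combination of class budgets (tested). The
baseline budget (bEB, `baseline_eb()`) is the 100%-grass, full-sky-view
reference of the weather stations.

The daytime window is the eight hourly stamps 11:00-18:00 inclusive on
the fixed daylight-savings clock: the hottest part of the day and the time
urban design matters most for people outdoors.

## Cooling design scenarios

A scenario (`scenario_spec()`, convenience `cooling_scenario()`) raises
Tree Canopy to a target fraction — debited pro-rata from grass, bare
earth, roads and other paving, since the plans add trees over existing
ground and no debit rule is otherwise specified — and swaps asphalt
(α 0.10, ε 0.90) for cementic concrete (α 0.30, ε 0.75) on paved classes.
The bundled study-tract stand-ins are two synthetic compositions: a
dense-core tract at 2.2% canopy (→ 12.0%) dominated by paving, and a
suburban tract at 3.9% canopy (→ 24.6%) with substantial turf. Their
non-canopy splits are constructed, realistic values, not the real tract
compositions. `compare_designs()` reports per-day deltas with a paired
t-test (a zero-variance difference series is flagged and reported with
p = 1 rather than crashing); `rank_tracts()` ranks descending with ties
sharing the smaller rank and percentile $(N-\text{rank})/N\times100$ —
the printed percentile arithmetic of the original ranking does not match
an obvious formula, so this convention is documented rather than claimed
to match.

The canopy-to-call-rate mapping behind `emr_reduction_estimate()` is
deliberately **pluggable**: the regression linking canopy cover to
heat-related call frequency is external to this analysis, so the bundled
`example_canopy_call_mapping()` is a clearly-labelled illustrative
piecewise-linear lookup that echoes the reported ~40%/~50% reductions; it
must not be read as a fitted epidemiological relationship.

## Statistics

The statistical battery mirrors study practice: Shapiro-Wilk normality
checks (`normality_check()`); correlations with policy selection
(`correlate()`: Pearson when both series pass normality, Spearman
otherwise — always Spearman for tract-level call counts — and a
`log_pearson` policy applying log(x+1) to counts, zeros included);
between-period comparison by one-way ANOVA with Tukey HSD letters at
α = 0.05 (`period_compare()`). The letter display is computed from the
Tukey p-value matrix by maximal-clique assignment; the between-period test
is not named in the source study, so ANOVA + Tukey is a documented
conventional choice. Two-sided tests throughout. Degenerate inputs
(constant series, zero residual variance) return flags instead of errors.

## The synthetic-data generators

`gen_weather()` emulates the study's weather record: four heat events
(June 2005, July-August 2006, May 2010, August-September 2010) with
25/18/26 net Pre/EHE/Post days, period targets equal to the printed
daytime-window summaries (T~a~ 23.3 ± 3.8 / 29.7 ± 2.5 / 23.3 ± 3.9 °C,
RH 56.4/53.8/56.0%, wind 4.2/4.2/5.2 m s^-1^), a sinusoidal diurnal cycle
peaking mid-afternoon and anchored so the window mean equals the day
value, humidity in anti-phase, and two correlated stations (r = 0.9)
whose inputs are averaged before modelling. Sky probabilities are equal
across periods (0.5/0.3/0.2) because the study does not report sky
frequencies; holding them equal attributes the period contrast entirely
to the printed weather differences.

Finite samples are made faithful to the printed summary statistics by
design rather than by luck: day-level anomalies are a stratified normal
sample (fixed standardized quantiles) so each period reproduces its
target mean and SD exactly; the quantiles are dealt evenly across events
so no event is systematically hotter; humidity and wind quantiles are
paired to the temperature ranks through fixed scramble permutations (a
Latin-hypercube design whose joint sample is seed-invariant, with only
the calendar assignment randomized); and sky categories are stratified
within period × event × hour-of-day. All of this can be disabled
(`match_moments = FALSE`, `stratify_sky = FALSE`) for plain i.i.d.
sampling, which the tests use to verify large-n convergence to the
targets.

`gen_city()` draws 544 tract compositions from a Dirichlet mixture with
areas of 20-150 ha and exact multinomial pixel partitions at 0.6 m, so
extraction round-trips are exact by construction. `gen_emr_calls()` draws
daily tract calls as Poisson with a log-link on the standardized pEB
(default β = 0.5, baseline 2 calls/day, heat-related thinning 0.35);
negative-binomial dispersion is optional. Per-tract baselines are
explicitly arbitrary — no real call rates are published at this grain.

**What passing tests do and do not show.** The generators reproduce the
marginal structure the analysis assumes (period summaries, diurnal shape,
count coupling); they have no spatial autocorrelation between tracts, no
weather-reanalysis realism, no serial dependence of days beyond the
event calendar, and the call-budget coupling is cleaner than real
morbidity data — synthetic city-wide correlations run far higher than the
published 0.3-0.7 range. Green tests certify the machinery and its
calibrated agreement with the printed city-wide quantities, not
epidemiological validity on real data.

## Numerical choices and degenerate inputs

Respiratory losses floored at zero (hot/humid limit); evaporation floored
at zero (no condensation); aerodynamic resistance capped at 500 s m^-1^
in calm air; humidity clamped to [0, 100] and wind to small positive
values after anomaly draws; rank ties share the smaller rank; zero-variance
paired comparisons and correlations return flags; Shapiro-Wilk is limited
to its 3-5000 support; strict greyscale legends raise on unknown levels
with the offending value. Proportion sums are validated at 10^-9^ and
design scenarios conserve proportion mass to 10^-12^ (tested).

## Problem sizes

The bundled study conditions are deliberately compact: 69 days × 24 h of
two-station weather, 544 tracts, five class micro-environments, and the
property suite uses 1000-case oracle sweeps, 2000-replicate type-I
simulations and 50-replicate coupling-recovery runs. The full test suite
and the acceptance script each complete in about a minute on one CPU.

## Known limitations

Steady-state physiology only (no core-temperature dynamics or transient
exposure); buildings contribute no radiation; walls are air-temperature
blackbodies; a single canopy transmissivity for all species; the
canopy-call lookup is illustrative; tract re-rankings depend on the
synthetic city, so the specific published rank changes (1st → 176th of
544, etc.) are not reproduced — only the qualitative cooling-induced
re-ranking is.
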