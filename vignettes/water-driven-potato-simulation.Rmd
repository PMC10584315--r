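---
title: "Water-driven potato growth simulation and drip irrigation scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-driven potato growth simulation and drip irrigation scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquadrip)
```

## The model

`aquadrip` implements a daily, water-driven crop growth simulator for potato
under drip irrigation in arid environments, in the AquaCrop tradition. The
production chain runs in four steps each day:

1. **Atmospheric demand.** Grass-reference evapotranspiration from the FAO-56
   Penman–Monteith combination equation,
   $$ET_0 = \frac{0.408\,\Delta (R_n - G) +
   \gamma \frac{900}{T + 273} u_2 (e_s - e_a)}
   {\Delta + \gamma (1 + 0.34 u_2)},$$
   with the Tetens saturation curve, $e_s$ as the mean of the saturation
   pressures at the daily extremes, $e_a$ reduced from mean relative
   humidity, net radiation from an Angstrom shortwave model
   ($a_s = 0.25$, $b_s = 0.50$) on sunshine duration plus a
   Stefan–Boltzmann longwave balance, $G = 0$ at the daily step, and
   pressure-dependent $\gamma$ from station altitude.

2. **Canopy.** Green canopy cover $CC$ grows on thermal time from $CC_0$
   (0.9 %) at emergence at relative rate $CGC$, saturating at $CC_x$ (94 %),
   and declines after the senescence day along
   $CC = CC_x\,[1 - 0.05(e^{(CDC/CC_x)\,GDD} - 1)]$.
   Water stress scales expansion by $K_{s,exp}$ and, past the senescence
   threshold, erodes cover at the attenuated rate $CDC (1 - K_{s,sen})$.

3. **Soil water.** A layered bucket balance over the root zone: infiltration
   cascades excess above field capacity downward (deep drainage below the
   profile), soil evaporation draws on a thin surface depth, transpiration
   is extracted across rooted layers in proportion to plant-available
   water. Depletion $D_r$ relative to total available water
   $TAW = \sum (\theta_{fc} - \theta_{wp})\,\Delta z$ drives the stress
   coefficients through crop-specific thresholds $p$.

4. **Production.** Transpiration $Tr = K_s\,(CC^{*} K_{cTr,x})\,ET_0$,
   biomass $B = WP^{*} \sum Tr/ET_0$, yield $Y = f_{HI}\,HI_0\,B$, and
   water use efficiency $WUE = Y/ET$ in kg of fresh tuber per m³ of
   water consumed.

The calibrated parameter set (packaged as `table4_crop_params`) is taken as
given: $K_{cTr,x} = 1.15$, $WP^{*} = 20$ g m⁻², $HI_0 = 55$ %, maximum root
depth 0.45 m, stress thresholds 0.26/0.66 (expansion), 0.65 (stomata),
0.69 (senescence), thermal limits 10/35 °C.

## Design choices where the design was open

**Canopy clock.** The parameter table prints $CGC$ with a per-day unit and
$CDC$ per growing degree day. Read literally as a relative rate per
calendar day, $CGC = 0.966\,\%$/d takes over 400 days to bring the canopy
from 0.9 % to half cover — no season would ever close canopy, contradicting
the observed phenology the calendar anchors encode (cover still small at
50 days after planting, maximal around 110 DAP, growth ceased by ~140 DAP).
Both clocks therefore run on thermal time: $CGC = 0.966$ % per GDD
(a relative rate of 0.00966 GDD⁻¹), matching $CDC$'s printed unit and
reproducing the observed trajectory (half cover near 45–60 DAP, plateau
before 110 DAP at typical 10–15 GDD/day). We treat the "%/d" unit as a
misprint rather than rescaling the printed number.

**Phase calendar.** Emergence 20 DAP, maximum canopy 110 DAP, senescence
onset 115 DAP, maturity 150 DAP (planting April 30, harvest September 27).
Only the 50/110/140-DAP anchors are observed; the rest interpolate.

**Stress-response shape.** `stress_coefficient()` offers linear and convex
transitions. The simulation default is convex (curve shape 3), the standard
crop-model choice: moderate depletion costs little, stress bites
progressively toward the lower threshold. A linear expansion response
between 26 % and 66 % depletion of a 18–43 mm TAW root zone stalls canopy
growth at depletion levels that drip-irrigated potato tolerates in
practice, and cannot produce near-full cover under any of the study's
irrigation levels.

**Soil evaporation under drip.** Evaporative demand is
$K_e \min(1 - CC,\, f_w)\,ET_0$ with $K_e = 1.10$ and wetted/exposed
fraction $f_w = 0.3$, drawing on the top 0.10 m of soil with a quadratic
drying coefficient between field capacity and an air-dry floor of
$0.5\,\theta_{wp}$. Drip emitters (one per plant) wet a small fraction of
the surface; letting stage-1 evaporation act on the whole surface
evaporates most of each irrigation and rainfall event and starves the
crop, which is neither observed nor intended by the original experiment.

**Other closures.** Transpiration demand is computed first and capped by
available soil water; biomass uses the realized flux. $f_{HI} = 1$ by
default (no stress adjustment rule is published; `f_hi` is exposed).
Dry-to-fresh conversion uses a tuber dry-matter fraction of 0.11, implied
by the ratio of published fresh yields to dry biomass
($HI_0 \cdot B / Y \approx 0.109$); it is a configuration knob, not a
published constant. The published per-scheme WUE column is internally
inconsistent with $100\,Y/ET$ computed from the same rows by 1–3 %
(presumably unrounded internal values); the package always computes WUE
from its own $Y$ and $ET$. Waterlogging, salinity, fertility and cold
stress are not modelled: the site is arid and quotas are at most 24 mm.
Initial soil water defaults to field capacity at planting (regional
pre-season irrigation practice); it is exposed via `initial_water`.

## The synthetic weather generator

No public accession exists for the 2015–2020 station records the original
scenario study used, so the scenario engine runs on a seeded stochastic
generator (`generate_weather()` with the `ningxia_climate()` preset)
emulating the stated climate of the central arid zone of Ningxia: about
270 mm mean annual rainfall with ~238 mm in May–October (the two recorded
growing seasons measured 234.2 and 266.6 mm), high evaporative demand, a
large diurnal temperature range, station altitude 1489 m.

Rainfall is monthly Bernoulli occurrence with Gamma event depths
(shape 0.7, scale 12 mm — few, convective events, as observed in arid
continental summers); temperatures are annual cosine cycles with a shared
AR(1) daily anomaly (tmax ≥ tmin by construction, diurnal floor 5 °C);
humidity is monthly means with Gaussian noise; wind is log-normal
(median 2 m/s); sunshine is a noisy fraction (0.68) of astronomical
daylength, halved on wet days. A single integer seed makes every series
bit-reproducible.

The generator reproduces totals and seasonality, not spectral or
extreme-event structure: no multi-day storm persistence, no heat waves
correlated with drought, no trend. Passing tests on synthetic weather
therefore validate the simulator's internal consistency (conservation,
monotone response to water, canopy shape) — not the absolute yield levels
of any particular historical year, which also depend on the original
station records and on unpublished internals of the reference
implementation. The published scenario result tables are packaged verbatim
as evidence (`table6_scenarioI`, `table7_scenarioII`) and drive the
selection and curve-fitting reproductions independently of the simulator.

## Numerical choices

- Negative computed $ET_0$ (rare winter radiative artifacts) clamps to zero
  with a warning.
- Water balance closes to machine precision by construction; the test
  suite enforces 10⁻⁶ mm over random seasons and 10⁻⁹ mm per day.
- The canopy plateau snaps to $CC_x$ exactly once within 0.2 percentage
  points, so the unstressed maximum equals the calibrated 94 % rather than
  approaching it asymptotically.
- Depletion may exceed TAW when evaporation dries the surface below
  wilting; relative depletion is clamped at 1 inside the stress curves.
- Scheme selection breaks ties toward less total irrigation water, then
  scheme order — an extra 600 m³/ha for a few percent of yield is not
  worthwhile in a water-scarce region.
- Quadratic yield-response fitting uses ordinary least squares
  (`stats::lm`); with totals in the 600–2880 m³/ha range the design matrix
  is well-conditioned at this scale, and the independent normal-equations
  oracle in the tests solves in a centred basis.

## Problem sizes

The test suite exercises 1000-day random checks for the ET0 chain and the
goodness-of-fit statistics, 100 random 60-day seasons for conservation,
50 synthetic years for generator climatology, and full 150-day season
simulations for the engine properties. The acceptance script runs the
complete 30-scheme grid over 6 synthetic years (180 season simulations).

## Worked example

```{r example, eval = FALSE}
site <- site_info(latitude = 36.8, altitude = 1489)
weather <- attach_et0(
  generate_weather(ningxia_climate(), years = 1, seed = 42,
                   start_year = 2020), site)
soil <- soil_profile(load_fixture("table3_soil"))
crop <- crop_parameters()
plan <- build_fixed_plan("2020-05-18", quota_mm = 20, cycle_days = 7,
                         n_events = 9)
sim <- run_simulation(weather, soil, crop, plan, "2020-04-30")
sim
```

## Known limitations

- Absolute yields for any historical year are not reproducible without the
  original station weather; the package's claims are structural
  (conservation, monotonicity, selection logic, response-curve shape).
- The yield decline beyond ~2500 m³/ha reported by the original scenario
  study is not an emergent property of this simulator: without a
  waterlogging or leaching mechanism, more water never hurts. The decline
  is preserved in the packaged result tables and recovered by the
  quadratic fit on them.
- Soil evaporation is a two-parameter approximation, not a full two-stage
  Ritchie model; drainage is an instantaneous cascade with no travel time;
  there is no capillary rise.
- The thermal-time reading of $CGC$ is this package's resolution of a
  unit ambiguity, documented above.
```
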