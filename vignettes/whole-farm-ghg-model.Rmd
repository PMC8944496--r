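---
title: "The whole-farm model behind flockfoot: assumptions, parameters, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The whole-farm model behind flockfoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockfoot)
```

`flockfoot` simulates one farm-year of a dairy sheep or goat system and
reports its greenhouse-gas, nutrient, water, energy and land footprints.
This vignette explains the model itself: what is being assumed, which
parameters matter, how the synthetic-data generators relate to real farms,
and where the edges of the model are.

## The modelling approach

The model is *empirical*, not mechanistic. Its core is a small set of
ordinary least-squares regressions estimated on flock-book records,
metabolic-chamber balances and forage field trials from continental
Mediterranean dairy-sheep country, wired together with standard
emission-factor accounting (IPCC-style Tier 2 for enteric methane, fixed
per-kilogram factors for everything purchased). This buys robustness and
transparency at the cost of mechanistic detail: every prediction can be
audited back to a printed coefficient in a CSV.

All sub-models are evaluated through one shared linear evaluator
(`eval_linear()`), with the coefficients in
`inst/extdata/model_coefficients.csv`:

* **Herd demography.** Annual replacement females, born offspring, culled
  offspring, adult losses and offspring deaths are linear in the present
  females (PF). At small PF some lines go negative; predictions are clamped
  at zero and the raw values kept as a `raw` attribute for diagnostics.
* **Excreta.** Feces (g DM/head/d) from diet OMD, DM, protein and NDF
  intake; urine volume and fecal/urinary N from N intake alone. The model
  stores OMD as a fraction and converts to percent internally, because the
  feces regression was fitted with OMD in percent. Note a structural quirk:
  the fecal-N and urinary-N lines were fitted independently, so near the
  design mean their sum slightly exceeds N intake (6.32 + 15.33 vs 20.9
  g/d). The predictions are reported as fitted — rescaling them would
  silently change the published lines — and an `n_excess` flag is attached
  so callers can decide.
* **Forage yield.** Triticale from plant height, days to inflorescence
  emergence and basal N; oats from height alone. Where two conflicting
  printed values exist for a coefficient (this happens for the feces
  intercept, the oats intercept sign, and a few slopes), the complete
  model-string versions are shipped; since all coefficients live in one CSV,
  swapping any choice is a one-line edit, not a code change.
* **Growth.** Gompertz curves for lamb and kid live weight
  (sheep: asymptote 68.59 kg, shape 2.47, rate 0.01/d; goats: 53.3, 1.9,
  0.0046/d). The 35-day slaughter weight used for meat-output bookkeeping
  comes from these curves.
* **Milk from genetic value.** Liters per lactation = 198.3 + 5.3 · GV,
  the hinge of the genetic-improvement scenarios.

The fitting procedure that produced these models is itself part of the
package (`fit_stepwise()`): forward selection at 5% significance keeping
the highest-R² candidate, rejecting predictors whose variance inflation
factor exceeds 10, and reporting the Durbin–Watson statistic. Ties are
broken toward fewer predictors, then lexical order, so refits are
deterministic.

## Emission accounting

**Enteric methane** uses the gross-energy route: Ym = 9.75 − 0.05 · OMD(%)
(6.5% at the 65% reference digestibility), and
CH₄ = DMI · (Ym/100) · (18.55/55.65), with 18.55 MJ/kg the gross-energy
density of feed DM and 55.65 MJ/kg the energy content of methane.

**The nitrogen cascade** starts from excreted N, split housed/grazing by
the grazing-time fraction. Housing NH₃ is 10% of excreted N, grazing NH₃
12%; N₂O follows at 0.0015 kg/kg NH₃ (housing) and 2.5% of grazing N net of
its NH₃. Soil N₂O uses 0.3% of applied manure N and 1% of fertilizer and
residue N (direct), 0.5% of redeposited volatilized N and 2.5% of leached N
(indirect), all as N₂O-N converted with 44/28. Two units decisions deserve
flagging: the source factors are printed as "g N-N₂O kg⁻¹" but are
dimensionally implausible as grams and are implemented as percentages
consistent with their IPCC provenance; and the fertilizer-manufacture
factor (5 g N₂O per kg N) is stated directly as N₂O mass and therefore not
converted.

**Leaching** needs drainage. The source text derives drainage from
"evapotranspiration minus rainfall", which is negative in this climate for
most of the year; the model uses the water-balance convention
max(0, rainfall − ETc), summed monthly. The leached fraction of applied N
grows at 0.1% per mm of drainage, capped at 30% — a deliberately simple,
configurable stand-in for a functional form that was never published.

**Embedded CO₂** applies per-item factors (diesel 3.31 kg/L, electricity
0.65 kg/kWh, N/P₂O₅/K₂O fertilizer 6.2/0.93/0.51 kg/kg, forage 0.2,
concentrate 0.3, plastics 2, purchased animals 11 kg/kg, pesticides
22.2 kg/ha, milk replacer 9.73 kg/kg). Unreported diesel defaults to
37 L/LU/year; unreported electricity to 0.055 kWh per lactating female per
milking minute per year, a package default chosen so a 100-ewe, 120-minute
parlor lands in the literature range for small dairy flocks (~660 kWh/yr).

**Carbon sequestration** books 45% of residue DM plus 13.4 kg C per kg of
manure N applied, times a humification coefficient (default 0.1, a
configurable package default), as negative CO₂ (×44/12). Cereal stubble and
straw contribute a fixed 1758 kg DM/ha, maize 19% of harvest, alfalfa 34%.

**Aggregation** weighs CH₄ ×28 and N₂O ×298. The total carbon footprint is
TCF = PCF + SY + iLUC − CS, where SY is the soybean burden (2.98 kg CO₂/kg)
and iLUC charges 143 g CO₂/m²·yr of off-farm feed area derived from
reference crop yields. The TCF identity is enforced exactly and tested on
every simulated farm.

## Functional units and allocation

Footprints are reported per hectare, per livestock unit, per present female
and per liter of FPCM (volume normalized to 6.5% fat / 5.8% protein by
0.25 + 0.085·fat + 0.035·protein, which is ~1.0055 at the reference
composition). Milk/meat allocation uses AF = 1 − 5.7717 · R with R the
meat/milk mass ratio, clamped to [0, 1]; meat-only farms are out of scope.
The allocation is applied to the per-liter unit only: per-hectare and
per-LU figures report the unallocated farm total, since both products leave
the same land and herd. LU conversion coefficients are not standardized in
the source material; the shipped defaults (adult 0.15, replacement 0.09,
lamb/kid 0.05) keep survey stocking densities in a plausible range and are
user-replaceable.

## The synthetic-farm generator

`gen_farm()` draws a farm from the per-breed survey means and standard
deviations (land blocks, herd classes, purchases, grazing time, milk yield
and composition, fertilization). Design choices worth knowing:

* **Truncated normals with moment matching.** Several survey fields have
  sd > mean (maize area 6 ± 22.7 ha); naive truncation at zero would
  inflate the generated means. The generator shifts the location parameter
  so the *truncated* mean equals the survey mean, which reproduces both the
  long-run average and the observed pile-up of zeros.
* **Internal consistency by rescaling.** Cropped blocks are rescaled into
  the arable area, lactating+replacement into the census (lactating ≈ 62%
  of adults in the survey), and the lactating lot is split 46/29/25% into
  high/medium/low production.
* **Herd-coupled meat sales.** Live weight sold follows the herd (culled
  offspring at the 35-day Gompertz weight plus a 5% adult cull) rather than
  an independent per-hectare draw; independent draws produce meat/milk
  ratios that push the allocation factor to its clamp, which no surveyed
  farm shows.
* **Genetic value.** Per-flock breeding values are not public; the default
  index of 9 places the +5/10/15% genetic-improvement herd cuts inside the
  0.47–2.38% band reported for these flocks, and is the package's
  calibrated default.

What the generator does **not** emulate: between-farm correlation structure
(fields are drawn independently apart from the consistency rescaling),
multi-year dynamics, and within-year feeding seasonality. Passing tests on
synthetic farms therefore demonstrate internal consistency and correct
accounting — not predictive skill on any particular real farm.

`gen_metabolic_trials()` and `gen_forage_trials()` regenerate the fitting
datasets of the excreta and forage models: predictors from the published
design moments, responses from the published lines plus Gaussian noise at
the published residual standard errors. Refitting them is the package's
round-trip check that the shipped coefficients and their uncertainties are
mutually coherent; with noise disabled the responses sit exactly on the
lines.

## Scenarios

`apply_scenario()` is pure (the baseline is never mutated; changes are
returned in a `diff` attribute). Breed restrictions are enforced: genetic
improvement applies to the autochthonous sheep group only, grazing
scenarios not to goats. Two calibrations are prescribed rather than
emergent: the default temperature-response table is set so +2 °C yields a
0.46% annual milk loss (the response equations themselves are unpublished,
so the table is the interface), and the genetic-value default above. The
grazed-triticale scenario substitutes purchased forage one-for-one with
pasture intake; without that substitution the scenario would add feed on
top of the unchanged ration and raise emissions, which is not the practice
being modelled. Scenario tables report whatever the model yields; published
scenario tables for these systems are treated as illustrative context, not
as calibration targets, because the underlying farm inputs are not public.

## Numerical conventions and degenerate inputs

* Count/mass predictions clamp at zero; raw values are preserved.
* Fraction-vs-percent confusions fail fast: `excreta_predict()` rejects
  OMD > 1, `ym()` rejects OMD ≤ 1.
* Zero denominators (area, milk, intake) raise errors rather than returning
  infinities; per-FU entries with zero denominators are `NA`.
* Nash–Sutcliffe efficiency is implemented unbounded below (the
  "varies from −1 to 1" phrasing sometimes seen is not the statistic's
  actual range); MBE is simulated − observed, so positive means
  overestimation.
* The stepwise fitter is seed-free and deterministic; ledger totals are
  permutation-invariant.

## Problem sizes used in the test suite

The suite runs the full farm pipeline on code-built fixture farms and a
few hundred generator draws; coefficient-recovery checks use the published
design sizes (n = 19–510) with 120 seeded replicates per model, requiring
each coefficient's 2-standard-error coverage to reach 90%. These sizes make
the whole suite run in well under a minute on one core while keeping the
binomial noise of the coverage checks small.

## Known limitations

* Milk production does not feed back into intake or requirements; the
  temperature scenario reduces milk (and hence per-liter footprints) but
  not feed use, so its per-hectare effect is near zero by construction.
* Excreta regressions come from ewes fed at maintenance; applying them to
  high-yielding lactating animals extrapolates beyond the fitting data.
* Crop water requirements (ETc) are inputs, not modelled; the water
  footprint is only as good as the supplied climate records and the
  per-product water table.
* The fertilization module is a nutrient-requirement balance; it does not
  reproduce regional fertilizer recommendation tables.
* No economics, no uncertainty propagation, single farm-year horizon.
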