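# flockfoot

Whole-farm greenhouse-gas and nutrient footprint simulation for dairy
sheep and goat farms.

Dairy small-ruminant systems — autochthonous dairy sheep (Manchega-type),
intensively housed foreign dairy sheep (Lacaune/Assaf-type), and dairy goats
— emit methane from enteric fermentation and manure, nitrous oxide from
manure and soils, and carbon dioxide embedded in purchased feed, fertilizer
and energy. `flockfoot` is an empirical whole-farm model for advisers,
agronomists and researchers who need farm-gate footprints and a quick
reading of which management changes actually move them.

## What it computes

Starting from one farm-year description (land, herd, purchases, grazing,
milk, monthly climate), the simulator chains:

* **Empirical sub-models** — herd demography from the number of present
  females (e.g. born offspring = −112.1 + 1.91 · PF); excreta of adult ewes
  from metabolic-chamber regressions (feces from OMD and intake composition;
  urine = −654.1 + 71.3 · N intake; fecal N = 1.30 + 0.24 · N intake;
  urinary N = 1.95 + 0.64 · N intake); triticale and oat forage yield from
  plant height, days to ear emergence and basal N; Gompertz lamb/kid growth;
  milk per lactation from the flock genetic value (198.3 + 5.3 · GV).
* **Enteric methane (Tier 2)** — Ym = 9.75 − 0.05 · OMD(%), then
  CH₄ (g/d) = DMI · (Ym/100) · (18.55/55.65).
* **Nitrogen cascade** — NH₃ from housing (0.1 kg/kg excreted N) and grazing
  (0.12), N₂O from manure management, grazing returns, soil applications
  (manure 0.3%, fertilizer and residues 1% as N₂O-N), volatilization (0.5%)
  and drainage-driven nitrate leaching (2.5%).
* **Embedded CO₂** — diesel (3.31 kg/L, default 37 L/LU), electricity
  (0.65 kg/kWh from lactating females × milking minutes), fertilizers, feed,
  plastics, purchased animals, pesticides; silage plastics and fermentation;
  soybean (2.98 kg/kg) and indirect land-use change (143 g CO₂/m² of
  off-farm feed area); minus soil carbon sequestration from residues and
  manure.
* **Assessment** — CO₂e (CH₄ × 28, N₂O × 298) as partial and total carbon
  footprints (TCF = PCF + SY + iLUC − CS) per hectare, livestock unit,
  present female and liter of fat- and protein-corrected milk (FPCM, 6.5%
  fat / 5.8% protein) with milk/meat allocation AF = 1 − 5.7717 · R;
  farm-gate N and P balances; acidification (SO₂e) and eutrophication
  (NO₃e) potentials; water, energy and nitrogen footprints; land use.
* **Scenario engine** — genetic improvement, herd-inventory cuts, feed
  substitutions (soybean→peas, fibrous concentrates, milk replacer), forage
  management, milking-energy cuts and a +2 °C climate scenario, reported as
  % change per functional unit against the baseline.
* **Validation battery** — Willmott's index of agreement, Nash–Sutcliffe
  efficiency, RMSE, MBE and r², plus VIF/Durbin–Watson screening and the
  forward-stepwise fitting procedure used to build the sub-models.

Every coefficient ships in editable CSVs under `inst/extdata/` (see
`ff_factors()`), so any factor can be audited or overridden without touching
code.

## Worked example

```r
library(flockfoot)

farm   <- gen_farm(seed = 42, breed_group = "Manchega")  # synthetic survey farm
report <- simulate_farm(farm)
report
#> Whole-farm simulation (Manchega)
#>   herd: 3620 head, 408.9 LU, 2190 present females
#>   total CO2e: 4192592 kg/yr (PCF 3644566, SY 296125, iLUC 430047, CS 178146)
#>   per FU: 2307 kg/ha | 10254 kg/LU | 3.46 kg/L FPCM (AF 0.76)
```

The farm emits 4,193 t CO₂e over the year: the partial footprint (enteric
and manure CH₄, N₂O cascade, embedded CO₂) plus soybean and land-use-change
add-ons, minus 178 t of soil carbon sequestration. Per liter of corrected
milk the footprint is 3.46 kg CO₂e after allocating 76% of emissions to
milk — inside the 2–5.6 kg CO₂e/L range reported for these systems.

```r
tab <- run_scenarios(farm)
tab[c(1, 7, 12), c("scenario", "co2e_ha", "change_co2e_ha_pct")]
#>          scenario co2e_ha change_co2e_ha_pct
#> 1        baseline    2307               0.00
#> 7 soybean_to_peas    2147              -6.94
#> 12 triticale_grazing_100d 2296         -0.47
```

Replacing imported soybean with peas removes the soybean and
land-use-change lines and cuts per-hectare emissions by ~7%; feed-side
measures dominate, management tweaks (milking energy, herd cuts) move the
total by well under 1% — the qualitative ordering reported for these farms.

A thin command-line wrapper with `simulate`, `scenarios`, `synth` and
`factors` subcommands lives at `inst/cli/flockfoot.R`.

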