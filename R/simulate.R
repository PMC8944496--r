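#' Simulate one farm-year
#'
#' Runs the full chain on a farm description: herd size and livestock units;
#' the average diet assembled from own forage, purchased feed and grazing;
#' excreta from the metabolic-chamber regressions; enteric methane from diet
#' digestibility (Ym); the manure budget and its ammonia / nitrous-oxide
#' cascade; soil direct and indirect N2O with drainage-driven nitrate
#' leaching; embedded CO2 of purchased inputs; silage plastics and
#' fermentation; soil carbon sequestration; and finally the farm-gate N/P
#' balances, carbon / water / energy / nitrogen footprints, acidification and
#' eutrophication potentials, and land use.
#'
#' @param farm A [farm_config()].
#' @param diet Named list of diet choices: `concentrate` (feed-table name of
#'   the concentrate), `purchased_forage`, `grazing_feed`, and
#'   `grazing_intake_kg_d` (pasture DM intake while grazing, kg/head/day).
#' @param factors Factor list from [ff_factors()].
#' @param feed_table,models,lu_table,we_table,yield_table,fixation_table
#'   Coefficient tables; defaults are the shipped CSVs.
#' @return An object of class `farm_report`: list with `ledger`
#'   ([emission_ledger()]), `co2e`, `footprint` ([carbon_footprint()]),
#'   `balance` ([farm_n_p_balance()]), `manure` ([manure_budget()]),
#'   `nue`, `impacts`, `wen` (water/energy/N), `land_use`, `fpcm_L`,
#'   `allocation`, `herd` (lu, pf, demography) and `diet` (per-head totals).
#' @export
simulate_farm <- function(farm,
                          diet = list(),
                          factors = ff_factors(),
                          feed_table = ff_feed_table(),
                          models = ff_models(),
                          lu_table = ff_lu_table(),
                          we_table = ff_water_energy_table(),
                          yield_table = ff_yield_table(),
                          fixation_table = ff_fixation_table()) {
  validate_farm(farm)
  diet <- utils::modifyList(
    list(concentrate = "concentrate_conventional",
         purchased_forage = "vetch_oat_hay",
         grazing_feed = "pasture",
         grazing_intake_kg_d = 1.5), diet)

  area <- farm_area_ha(farm)
  lu <- livestock_units(farm$herd, lu_table)
  pf <- present_females(farm$herd)
  adult_equiv <- max(lu / 0.15, 1e-9)        # herd scaled to adult heads
  heads <- sum(farm$herd$counts)
  demo <- demography(pf, models)

  ## ---- diet assembly (kg DM/yr by feed-table class) ------------------------
  own <- own_forage_dm(farm)
  p <- farm$purchases
  components_kg <- c(own,
    stats::setNames(p$forage_kg, diet$purchased_forage),
    stats::setNames(p$concentrate_kg, diet$concentrate),
    soybean_meal = p$soybean_kg,
    peas = if (!is.null(p$peas_kg)) p$peas_kg else 0)
  graze_kg <- farm$grazing_time_fraction * pf * diet$grazing_intake_kg_d * 365
  components_kg <- c(components_kg,
                     stats::setNames(graze_kg, diet$grazing_feed))
  components_kg <- tapply(components_kg, names(components_kg), sum)
  components_kg <- components_kg[components_kg > 0]
  if (!length(components_kg)) stop("farm has no feed at all", call. = FALSE)
  per_head_day <- components_kg / adult_equiv / 365
  r <- ration(per_head_day, feed_table = feed_table)
  totals <- ration_totals(r, ge_mj_per_kg = factors$ge_mj_per_kg_dm)

  ## ---- excreta and enteric methane -----------------------------------------
  exc <- excreta_predict(totals$omd_weighted, totals$dmi_g, totals$gp_g,
                         totals$ndf_g, totals$n_g, models)
  scale_yr <- adult_equiv * 365
  feces_kg_dm <- exc$feces_g_dm * scale_yr / 1000
  urine_L <- exc$urine_ml * scale_yr / 1000
  n_excreted_kg <- (exc$n_feces_g + exc$n_urine_g) * scale_yr / 1000
  ym_pct <- ym(100 * totals$omd_weighted)
  ch4_enteric_kg <- enteric_ch4(totals$dmi_g, ym_pct,
                                factors$ge_mj_per_kg_dm,
                                factors$ch4_energy_mj_per_kg) *
    scale_yr / 1000

  ## ---- manure budget and animal-origin N gases -----------------------------
  bedding <- farm$bedding_straw_kg_per_female * pf
  manure <- manure_budget(feces_kg_dm, urine_L, bedding,
                          grazing_share = farm$grazing_time_fraction,
                          sold_kg = farm$manure_sold_kg, factors = factors)
  ch4_manure_kg <- manure_ch4(
    manure$housed_kg * factors$manure_dm_fraction,
    factors$manure_b0_m3_per_kg_vs, factors$manure_mcf,
    factors$manure_vs_fraction, factors$ch4_density_kg_m3)
  n_housed <- (1 - farm$grazing_time_fraction) * n_excreted_kg
  n_grazing <- farm$grazing_time_fraction * n_excreted_kg
  gases <- nh3_n2o_animal(n_housed, n_grazing, factors)

  ## ---- soil pathways --------------------------------------------------------
  sold_frac <- if (manure$housed_kg + manure$sold_kg > 0) {
    manure$sold_kg / (manure$housed_kg + manure$sold_kg)
  } else 0
  n_after_nh3 <- max(0, n_housed - gases$nh3_housing * 14 / 17)
  applied_manure_n <- n_after_nh3 * (1 - sold_frac)
  fert_n <- p$fertilizer_n_kg
  residue_dm <- residue_dm_kg(farm, factors)
  residue_n <- residue_dm * factors$bedding_straw_n_fraction
  drain <- drainage_mm(farm$climate)
  n_applied_ha <- if (area > 0) (applied_manure_n + fert_n) / area else 0
  leached_n <- leached_no3(n_applied_ha, drain, factors) * area
  forage_n <- p$forage_kg * 0.0176
  conc_n <- (p$concentrate_kg + p$soybean_kg) * 0.0272
  volatilized_n <- (gases$nh3_housing + gases$nh3_grazing) * 14 / 17
  n2o_soil <- soil_n2o(applied_manure_n, fert_n, residue_n, volatilized_n,
                       leached_n, forage_n, conc_n, fert_n, factors)

  ## ---- purchased-input CO2, silage, sequestration ---------------------------
  lact <- sum(farm$herd$counts[c("lactating_high", "lactating_medium",
                                 "lactating_low")])
  emb <- embedded_co2(p, lu = lu, lactating_females = lact,
                      milking_time_min = farm$milking_time_min,
                      factors = factors)
  sil <- silage_totals(farm, factors)
  cs_kg <- carbon_sequestration(residue_dm, applied_manure_n,
                                factors = factors)

  ## ---- off-farm land, iLUC, soybean ----------------------------------------
  milk_total_L <- farm$milk_sold_L +
    factors$milk_suckled_l_per_offspring * farm$herd$counts[["offspring"]]
  fpcm_L <- fpcm(milk_total_L, farm$milk_fat_pct, farm$milk_protein_pct,
                 factors)
  off_feed <- list(forage = p$forage_kg, concentrate = p$concentrate_kg,
                   soybean = p$soybean_kg)
  if (!is.null(p$peas_kg) && p$peas_kg > 0) off_feed$peas <- p$peas_kg
  off_feed <- off_feed[unlist(off_feed) > 0]
  on_feed_m2 <- 10000 *
    sum(farm$land$area_ha[farm$land$crop != "fallow"])
  lu_use <- land_use(off_feed, on_feed_m2, max(fpcm_L, 1e-9), yield_table)
  iluc_kg <- factors$iluc_kg_co2_m2 * lu_use$off_farm_m2
  sy_kg <- factors$co2_soybean_kg * p$soybean_kg

  ## ---- ledger ---------------------------------------------------------------
  led <- emission_ledger(
    category = c("enteric", "manure_mgmt", "housing_NH3_N2O", "grazing",
                 "soil_direct", "soil_indirect_volatilization",
                 "soil_indirect_leaching", "fertilizer_manufacture",
                 "purchased_feed_N2O", "purchased_inputs", "silage",
                 "soybean", "iLUC", "sequestration"),
    gas = c("CH4", "CH4", "N2O", "N2O", "N2O", "N2O", "N2O", "N2O", "N2O",
            "CO2", "CO2", "CO2", "CO2", "CO2"),
    kg = c(ch4_enteric_kg, ch4_manure_kg, gases$n2o_housing,
           gases$n2o_grazing,
           n2o_soil$direct_manure + n2o_soil$direct_fertilizer +
             n2o_soil$direct_residues,
           n2o_soil$indirect_volatilization, n2o_soil$indirect_leaching,
           n2o_soil$fertilizer_manufacture,
           n2o_soil$purchased_forage + n2o_soil$purchased_concentrate,
           emb$total, sil$total, sy_kg, iluc_kg, -cs_kg))

  ## ---- assessment -----------------------------------------------------------
  milk_kg_ha <- farm$milk_sold_L * factors$milk_density_kg_l / max(area, 1e-9)
  alloc <- allocation_factor(farm$live_weight_sold_kg / max(area, 1e-9),
                             max(milk_kg_ha, 1e-9), factors)
  fp <- carbon_footprint(led, area, lu, pf, fpcm_L, af = alloc$AF, factors)
  bal <- farm_n_p_balance(farm, milk_total_L = milk_total_L, manure = manure,
                          factors = factors, feed_table = feed_table,
                          fixation_table = fixation_table)
  items <- attr(bal, "items")
  nue <- nue_pue(
    n_milk = unname(items$n_outputs["milk"]),
    n_meat = unname(items$n_outputs["meat"]),
    n_intake = totals$n_g * scale_yr / 1000,
    p_milk = unname(items$p_outputs["milk"]),
    p_meat = unname(items$p_outputs["meat"]),
    p_intake = totals$p_g * scale_yr / 1000)

  nh3_total <- gases$nh3_housing + gases$nh3_grazing
  n2o_total_kg <- sum(led$kg[led$gas == "N2O"])
  imp <- impact_potentials(nh3_kg = nh3_total,
                           no3_kg = leached_n * 62 / 14, factors = factors)
  reactive <- c(nh3_n = nh3_total * 14 / 17,
                n2o_n = n2o_total_kg * 28 / 44,
                no3_n = leached_n)
  wen <- water_energy_n_footprints(
    farm, imports = off_feed, milk_L = milk_total_L, heads = heads,
    diesel_L = attr(emb, "diesel_L"),
    electricity_kwh = attr(emb, "electricity_kwh"),
    n_imported_kg = sum(items$n_inputs), reactive_n_kg = reactive,
    factors = factors, we_table = we_table)

  structure(list(
    ledger = led, co2e = co2e(led, factors), footprint = fp, balance = bal,
    manure = manure, nue = nue, impacts = imp, wen = wen, land_use = lu_use,
    fpcm_L = fpcm_L, allocation = alloc,
    herd = list(lu = lu, pf = pf, heads = heads, demography = demo,
                stocking_lu_ha = if (area > 0) lu / area else NA_real_),
    diet = c(totals, list(ym_pct = ym_pct, components_kg = components_kg)),
    farm = farm), class = "farm_report")
}

# Own-grown forage DM (kg/yr) by feed-table class, from the land base.
own_forage_dm <- function(farm) {
  if (!nrow(farm$land)) return(numeric())
  cls <- character(nrow(farm$land))
  for (i in seq_len(nrow(farm$land))) {
    crop <- farm$land$crop[i]; use <- farm$land$use[i]
    cls[i] <- if (use == "grazing" && crop != "fallow") "triticale_pasture"
    else switch(crop,
      barley_grain = "barley_grain",
      oats_forage = "oat_hay",
      triticale_forage = if (grepl("silage", use)) "triticale_silage"
        else "oat_hay",
      vetch_oat = "vetch_oat_hay",
      maize_silage = "maize_silage",
      alfalfa = "alfalfa_hay",
      legumes = "vetch_oat_hay",
      fallow = NA_character_)
  }
  kg <- 1000 * farm$land$area_ha * farm$land$yield_t_dm_ha
  keep <- !is.na(cls) & kg > 0
  if (!any(keep)) return(numeric())
  tapply(kg[keep], cls[keep], sum)
}

# Plant residue DM reaching the soil (kg/yr): cereal stubble+straw at the
# fixed per-ha figure, maize at 19% of harvest, alfalfa at 34%.
residue_dm_kg <- function(farm, factors = ff_factors()) {
  if (!nrow(farm$land)) return(0)
  res <- 0
  for (i in seq_len(nrow(farm$land))) {
    crop <- farm$land$crop[i]
    a <- farm$land$area_ha[i]
    harvest <- 1000 * a * farm$land$yield_t_dm_ha[i]
    res <- res + switch(crop,
      barley_grain = , oats_forage = , triticale_forage = , vetch_oat =
        a * factors$stubble_straw_kg_dm_ha,
      maize_silage = harvest * factors$maize_residue_fraction,
      alfalfa = , legumes = harvest * factors$alfalfa_residue_fraction,
      fallow = 0)
  }
  res
}

# Silage plastics + fermentation CO2 over the land base (kg CO2/yr).
silage_totals <- function(farm, factors = ff_factors()) {
  total <- 0
  plastic <- ferment <- 0
  if (nrow(farm$land)) {
    for (i in seq_len(nrow(farm$land))) {
      use <- farm$land$use[i]
      if (!grepl("silage", use)) next
      crop <- if (farm$land$crop[i] == "maize_silage") "maize" else "cereal"
      dm_t <- farm$land$area_ha[i] * farm$land$yield_t_dm_ha[i]
      fresh_t <- dm_t / 0.35                  # silage at 35% DM
      method <- if (use == "silage_bag") "bag" else "round_bale"
      s <- silage_co2(fresh_t, method, crop, dm_fraction = 0.35,
                      factors = factors)
      plastic <- plastic + s$plastic_co2
      ferment <- ferment + s$fermentation_co2
    }
  }
  list(plastic_co2 = plastic, fermentation_co2 = ferment,
       total = plastic + ferment)
}

#' @export
print.farm_report <- function(x, ...) {
  fp <- x$footprint
  cat("Whole-farm simulation (", x$farm$breed_group, ")\n", sep = "")
  cat(sprintf("  herd: %d head, %.1f LU, %d present females\n",
              x$herd$heads, x$herd$lu, x$herd$pf))
  cat(sprintf("  total CO2e: %.0f kg/yr (PCF %.0f, SY %.0f, iLUC %.0f, CS %.0f)\n",
              fp$tcf_kg_co2e, fp$pcf_kg_co2e, fp$sy, fp$iluc, fp$cs))
  cat(sprintf("  per FU: %.0f kg/ha | %.0f kg/LU | %.2f kg/L FPCM (AF %.2f)\n",
              fp$per_fu[["ha"]], fp$per_fu[["LU"]], fp$per_fu[["L_FPCM"]],
              fp$af))
  invisible(x)
}

#' Write simulation reports
#'
#' `write_report_json()` serializes the full report; `write_ledger_csv()`
#' writes the emission ledger with CO2e per entry.
#'
#' @param report A [simulate_farm()] result.
#' @param path Output file.
#' @param factors Factor list (for the CO2e column).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- report[setdiff(names(report), "farm")]
  out$ledger <- as.data.frame(report$ledger)
  out$balance <- as.data.frame(report$balance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_ledger_csv <- function(report, path, factors = ff_factors()) {
  led <- as.data.frame(report$ledger)
  gwp <- c(CO2 = 1, CH4 = factors$gwp_ch4, N2O = factors$gwp_n2o)
  led$kg_co2e <- led$kg * gwp[led$gas]
  utils::write.csv(led, path, row.names = FALSE)
  invisible(path)
}
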