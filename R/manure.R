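#' Annual manure budget
#'
#' Splits the year's excreta between the housed pool (collected with bedding
#' straw, storable and spreadable or saleable) and the pasture pool (deposited
#' directly while grazing), on a fresh-mass basis.  Feces arrive as dry
#' matter and are converted to fresh mass with the 35% manure DM assumption;
#' urine is taken at 1 kg/L.  N, P and K contents of the grazing-deposited
#' pool use the printed 0.55%, 0.07% and 1.1% concentrations; housed-pool
#' concentrations are configurable defaults.
#'
#' @param feces_kg_dm Herd total feces (kg DM/year).
#' @param urine_L Herd total urine (L/year).
#' @param bedding_kg Bedding straw entering the manure (kg/year).
#' @param grazing_share Fraction of excreta deposited on pasture, in [0, 1].
#' @param sold_kg Manure sold (kg fresh/year); must not exceed the housed pool.
#' @param factors Factor list from [ff_factors()].
#' @return An object of class `manure_budget`: fresh-mass pools
#'   (`housed_kg`, `pasture_kg`, `sold_kg`, `produced_kg`, `bedding_kg`) and
#'   nutrient masses (`n_housed_kg`, `p_housed_kg`, `k_housed_kg`,
#'   `n_pasture_kg`, `p_pasture_kg`, `k_pasture_kg`, `n_sold_kg`, `p_sold_kg`).
#' @examples
#' b <- manure_budget(feces_kg_dm = 350, urine_L = 1000, bedding_kg = 225,
#'                    grazing_share = 0)
#' b$housed_kg  # feces fresh + urine + bedding
#' @export
manure_budget <- function(feces_kg_dm, urine_L, bedding_kg = 0,
                          grazing_share = 0, sold_kg = 0,
                          factors = ff_factors()) {
  assert_nonneg(c(feces_kg_dm, urine_L, bedding_kg, sold_kg), "manure masses")
  assert_fraction(grazing_share, "grazing_share")
  feces_fresh <- feces_kg_dm / factors$manure_dm_fraction
  produced <- feces_fresh + urine_L          # urine at 1 kg/L
  pasture <- grazing_share * produced
  housed_gross <- (1 - grazing_share) * produced + bedding_kg
  if (sold_kg > housed_gross + 1e-9) {
    stop("manure sold (", sold_kg, " kg) exceeds the housed pool (",
         round(housed_gross, 1), " kg)", call. = FALSE)
  }
  housed <- housed_gross - sold_kg
  conc <- function(pool_kg, n_pct, p_pct, k_pct) {
    c(n = pool_kg * n_pct / 100, p = pool_kg * p_pct / 100,
      k = pool_kg * k_pct / 100)
  }
  hz <- conc(housed, factors$housed_manure_n_pct, factors$housed_manure_p_pct,
             factors$housed_manure_k_pct)
  pz <- conc(pasture, factors$grazing_manure_n_pct,
             factors$grazing_manure_p_pct, factors$grazing_manure_k_pct)
  sz <- conc(sold_kg, factors$housed_manure_n_pct, factors$housed_manure_p_pct,
             factors$housed_manure_k_pct)
  structure(list(housed_kg = housed, pasture_kg = pasture, sold_kg = sold_kg,
                 produced_kg = produced, bedding_kg = bedding_kg,
                 n_housed_kg = unname(hz["n"]), p_housed_kg = unname(hz["p"]),
                 k_housed_kg = unname(hz["k"]),
                 n_pasture_kg = unname(pz["n"]), p_pasture_kg = unname(pz["p"]),
                 k_pasture_kg = unname(pz["k"]),
                 n_sold_kg = unname(sz["n"]), p_sold_kg = unname(sz["p"])),
            class = "manure_budget")
}

#' Farm-gate nitrogen and phosphorus balance
#'
#' Inputs sum purchased feed, mineral fertilizer, purchased animals (0.28 kg
#' N and 0.0065 kg P per kg live weight), atmospheric deposition (10 kg
#' N/ha/yr over all farmland), bedding straw, and symbiotic fixation by
#' legume crops.  Outputs sum milk (N as crude protein / 6.38 with milk
#' density 1.034 kg/L; P at 1.3 g/L), meat (live weight at the same animal
#' concentrations), wool (N 12.8% of weight, P 0.1 g/kg) and sold manure.
#' Surplus is inputs minus outputs, per hectare; efficiency is
#' 100 x outputs / inputs.
#'
#' @param farm A validated [farm_config()].
#' @param milk_total_L Total milk produced (marketed + suckled); defaults to
#'   `milk_sold_L` plus the offspring allowance.
#' @param wool_kg Wool sold (kg/yr), default 0.
#' @param manure Optional [manure_budget()] supplying sold-manure nutrients.
#' @param factors Factor list from [ff_factors()].
#' @param feed_table,fixation_table Composition/fixation tables.
#' @return An object of class `nutrient_balance`: a data frame with one row
#'   per element (`N`, `P`) and columns `inputs_kg_ha`, `outputs_kg_ha`,
#'   `surplus_kg_ha`, `efficiency_pct`, plus an `items` attribute itemizing
#'   every input/output in kg/yr.
#' @export
farm_n_p_balance <- function(farm, milk_total_L = NULL, wool_kg = 0,
                             manure = NULL, factors = ff_factors(),
                             feed_table = ff_feed_table(),
                             fixation_table = ff_fixation_table()) {
  validate_farm(farm)
  area <- farm_area_ha(farm)
  if (area <= 0) stop("farm has zero area: per-ha balance undefined",
                      call. = FALSE)
  p <- farm$purchases
  feed_n <- function(name) {
    row <- feed_table[feed_table$name == name, ]
    c(n = row$n, p = row$p)
  }
  # Purchased forage uses a representative hay composition; concentrates and
  # soybean use their table rows.
  forage_np <- c(n = 0.0176, p = 0.0023)
  conc_np <- feed_n("concentrate_conventional")
  soy_np <- feed_n("soybean_meal")
  bedding_total <- farm$bedding_straw_kg_per_female *
    present_females(farm$herd)

  fix_n <- 0
  if (nrow(farm$land)) {
    fx <- fixation_table$kg_n_ha[match(farm$land$crop, fixation_table$crop)]
    fx[is.na(fx)] <- 0
    fix_n <- sum(fx * farm$land$area_ha)
  }

  peas_np <- feed_n("peas")
  peas_kg <- p$peas_kg %||% 0
  in_n <- c(purchased_forage = p$forage_kg * forage_np["n"],
            purchased_concentrate = p$concentrate_kg * conc_np["n"],
            purchased_soybean = p$soybean_kg * soy_np["n"],
            purchased_peas = peas_kg * peas_np["n"],
            fertilizer = p$fertilizer_n_kg,
            purchased_animals = p$animals_liveweight_kg *
              factors$n_per_kg_liveweight,
            atmospheric = factors$atmospheric_n_kg_ha * area,
            bedding = bedding_total * factors$bedding_straw_n_fraction,
            fixation = fix_n)
  in_p <- c(purchased_forage = p$forage_kg * forage_np["p"],
            purchased_concentrate = p$concentrate_kg * conc_np["p"],
            purchased_soybean = p$soybean_kg * soy_np["p"],
            purchased_peas = peas_kg * peas_np["p"],
            fertilizer = p$fertilizer_p2o5_kg * 0.4364,  # P2O5 -> P
            purchased_animals = p$animals_liveweight_kg *
              factors$p_per_kg_liveweight,
            bedding = bedding_total * factors$bedding_straw_p_fraction)

  if (is.null(milk_total_L)) {
    milk_total_L <- farm$milk_sold_L +
      factors$milk_suckled_l_per_offspring * farm$herd$counts[["offspring"]]
  }
  milk_n <- milk_total_L * factors$milk_density_kg_l *
    (farm$milk_protein_pct / 100) / factors$milk_n_cp_divisor
  out_n <- c(milk = milk_n,
             meat = farm$live_weight_sold_kg * factors$n_per_kg_liveweight,
             wool = wool_kg * factors$wool_n_fraction,
             manure_sold = if (is.null(manure)) 0 else manure$n_sold_kg)
  out_p <- c(milk = milk_total_L * factors$milk_p_g_per_l / 1000,
             meat = farm$live_weight_sold_kg * factors$p_per_kg_liveweight,
             wool = wool_kg * factors$wool_p_g_per_kg / 1000,
             manure_sold = if (is.null(manure)) 0 else manure$p_sold_kg)

  mk <- function(el, ins, outs) {
    ti <- sum(ins); to <- sum(outs)
    if (ti == 0 && to == 0) {
      stop(el, " balance undefined: no inputs and no outputs", call. = FALSE)
    }
    data.frame(element = el, inputs_kg_ha = ti / area,
               outputs_kg_ha = to / area,
               surplus_kg_ha = (ti - to) / area,
               efficiency_pct = if (ti > 0) 100 * to / ti else NA_real_)
  }
  bal <- rbind(mk("N", in_n, out_n), mk("P", in_p, out_p))
  attr(bal, "items") <- list(n_inputs = in_n, n_outputs = out_n,
                             p_inputs = in_p, p_outputs = out_p)
  class(bal) <- c("nutrient_balance", "data.frame")
  bal
}

#' Soil nutrient balance and utilization efficiency
#'
#' Balance is inputs minus outputs (outputs = gaseous losses + leaching +
#' crop extractions); the utilization efficiency is
#' `100 * (extractions - plant residues) / (inputs - balance)`, undefined
#' when inputs equal the balance (i.e. no outputs).
#'
#' @param applied_kg Nutrient applied to the soil (organic + inorganic +
#'   deposition + fixation), kg/yr.
#' @param gaseous_kg Gaseous losses (NH3, N2O, NO, N2 as N), kg/yr.
#' @param leached_kg Leached losses, kg/yr.
#' @param extractions_kg Crop extractions, kg/yr.
#' @param residues_kg Nutrient returned in plant residues, kg/yr.
#' @return List with `inputs`, `outputs`, `balance`, `efficiency_pct`.
#' @export
soil_balance <- function(applied_kg, gaseous_kg = 0, leached_kg = 0,
                         extractions_kg = 0, residues_kg = 0) {
  assert_nonneg(c(applied_kg, gaseous_kg, leached_kg, extractions_kg,
                  residues_kg), "soil balance terms")
  outputs <- gaseous_kg + leached_kg + extractions_kg
  balance <- applied_kg - outputs
  if (abs(applied_kg - balance) < 1e-12) {
    stop("soil efficiency undefined: inputs equal balance (no outputs)",
         call. = FALSE)
  }
  list(inputs = applied_kg, outputs = outputs, balance = balance,
       efficiency_pct = 100 * (extractions_kg - residues_kg) /
         (applied_kg - balance))
}
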