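#' Emission ledger
#'
#' The additive backbone of every footprint: an append-only table of
#' (source category, gas, kg/yr) entries.  Gases are `CH4`, `N2O` and `CO2`;
#' carbon sequestration enters as a negative `CO2` mass in its own category,
#' every other mass must be non-negative.
#'
#' @param category,gas,kg Vectors describing entries to seed the ledger with.
#' @return An object of class `emission_ledger` (a data frame).
#' @export
emission_ledger <- function(category = character(), gas = character(),
                            kg = numeric()) {
  led <- data.frame(category = category, gas = gas, kg = kg,
                    stringsAsFactors = FALSE)
  class(led) <- c("emission_ledger", "data.frame")
  validate_ledger(led)
  led
}

FF_GASES <- c("CH4", "N2O", "CO2")

validate_ledger <- function(led) {
  if (nrow(led)) {
    bad <- setdiff(unique(led$gas), FF_GASES)
    if (length(bad)) {
      stop("unknown gas in ledger: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    neg <- led$kg < 0 & led$category != "sequestration"
    if (any(neg)) {
      stop("negative mass outside the sequestration category: ",
           paste(unique(led$category[neg]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(led)
}

#' @rdname emission_ledger
#' @param led An existing ledger.
#' @export
ledger_add <- function(led, category, gas, kg) {
  out <- rbind(led, data.frame(category = category, gas = gas, kg = kg,
                               stringsAsFactors = FALSE))
  class(out) <- c("emission_ledger", "data.frame")
  validate_ledger(out)
  out
}

#' Methane conversion factor from diet digestibility
#'
#' The share of gross energy intake lost as enteric methane (Ym, %):
#' `9.75 - 0.05 * OMD` with OMD in percent.  At the reference digestibility
#' of 65% this gives the default Ym of 6.5.
#'
#' @param omd_pct Organic matter digestibility in percent, in (0, 100].
#' @return Ym (%).
#' @export
ym <- function(omd_pct) {
  if (any(!is.finite(omd_pct)) || any(omd_pct <= 1) || any(omd_pct > 100)) {
    stop("omd_pct must be in percent (0, 100]; got ",
         paste(omd_pct, collapse = ", "),
         " (fraction-scale input?)", call. = FALSE)
  }
  9.75 - 0.05 * omd_pct
}

#' Enteric methane per head and day
#'
#' Tier-2 form: dry-matter intake times the methane conversion factor times
#' the ratio of feed gross-energy density (18.55 MJ/kg DM) to the energy
#' content of methane (55.65 MJ/kg).
#'
#' @param dmi_g_per_day Dry-matter intake (g/head/day).
#' @param ym_pct Methane conversion factor (%), from [ym()].
#' @param ge_mj_per_kg,ch4_energy_mj_per_kg Energy constants.
#' @return g CH4/head/day.
#' @examples
#' enteric_ch4(1000, 6.5)  # 21.67 g/day
#' @export
enteric_ch4 <- function(dmi_g_per_day, ym_pct, ge_mj_per_kg = 18.55,
                        ch4_energy_mj_per_kg = 55.65) {
  assert_nonneg(dmi_g_per_day, "dmi_g_per_day")
  dmi_g_per_day * (ym_pct / 100) * (ge_mj_per_kg / ch4_energy_mj_per_kg)
}

#' Manure methane
#'
#' Tier-2 chain from manure dry matter through volatile solids to CH4:
#' `DM x VS fraction x B0 x MCF x 0.67 kg/m3`.  Only the 35% manure DM is a
#' survey value; B0, MCF and the VS fraction ship as documented defaults for
#' solid sheep/goat manure and are configurable.
#'
#' @param manure_dm_kg Manure dry matter (kg/yr).
#' @param b0_m3_per_kg_vs Maximum CH4 producing capacity (m3/kg VS).
#' @param mcf_fraction Methane conversion factor of the storage system, [0,1].
#' @param vs_fraction Volatile solids per kg DM, [0,1].
#' @param ch4_density_kg_m3 Density of CH4 (kg/m3).
#' @return kg CH4/yr.
#' @export
manure_ch4 <- function(manure_dm_kg, b0_m3_per_kg_vs = 0.19,
                       mcf_fraction = 0.015, vs_fraction = 0.8,
                       ch4_density_kg_m3 = 0.67) {
  assert_nonneg(manure_dm_kg, "manure_dm_kg")
  assert_fraction(mcf_fraction, "mcf_fraction")
  assert_fraction(vs_fraction, "vs_fraction")
  manure_dm_kg * vs_fraction * b0_m3_per_kg_vs * mcf_fraction *
    ch4_density_kg_m3
}

#' Ammonia and nitrous oxide from housing and grazing
#'
#' Housing/storage: 0.1 kg NH3 per kg excreted N, then 0.0015 kg N2O per kg
#' NH3.  Grazing: 0.12 kg NH3 per kg excreted N, and 0.025 kg N2O per kg of
#' excreted N net of the grazing NH3.
#'
#' @param n_excreted_housed_kg,n_excreted_grazing_kg Excreted N (kg/yr) in
#'   housing and on pasture.
#' @param factors Factor list from [ff_factors()].
#' @return List with `nh3_housing`, `nh3_grazing`, `n2o_housing`,
#'   `n2o_grazing` (kg/yr).
#' @export
nh3_n2o_animal <- function(n_excreted_housed_kg, n_excreted_grazing_kg,
                           factors = ff_factors()) {
  assert_nonneg(c(n_excreted_housed_kg, n_excreted_grazing_kg), "excreted N")
  nh3_h <- factors$nh3_housing_per_n * n_excreted_housed_kg
  nh3_g <- factors$nh3_grazing_per_n * n_excreted_grazing_kg
  list(nh3_housing = nh3_h,
       nh3_grazing = nh3_g,
       n2o_housing = factors$n2o_per_nh3_housing * nh3_h,
       n2o_grazing = factors$n2o_per_grazing_n *
         (n_excreted_grazing_kg - nh3_g))
}

N2O_PER_N <- 44 / 28

#' Soil nitrous oxide by pathway
#'
#' Direct emissions from applied manure (0.3%), mineral fertilizer (1%) and
#' crop residues (1% of their N); indirect emissions from redeposited
#' volatilized N (0.5%) and leached N (2.5%); plus the upstream burdens of
#' fertilizer manufacture (5 g N2O/kg N, already in N2O mass) and of
#' purchased forage and concentrate N (2% and 1% as N2O-N).  All N2O-N
#' pathways are converted to N2O mass with 44/28.
#'
#' @param applied_manure_n,fert_n,residue_n,volatilized_n,leached_n N mass
#'   entering each pathway (kg N/yr).
#' @param purchased_forage_n,purchased_conc_n,purchased_fert_n N in purchased
#'   forage, concentrate and fertilizer (kg N/yr).
#' @param factors Factor list from [ff_factors()].
#' @return Named list of kg N2O/yr per pathway plus `total`.
#' @export
soil_n2o <- function(applied_manure_n = 0, fert_n = 0, residue_n = 0,
                     volatilized_n = 0, leached_n = 0,
                     purchased_forage_n = 0, purchased_conc_n = 0,
                     purchased_fert_n = 0, factors = ff_factors()) {
  args <- c(applied_manure_n, fert_n, residue_n, volatilized_n, leached_n,
            purchased_forage_n, purchased_conc_n, purchased_fert_n)
  assert_nonneg(args, "soil N2O inputs")
  out <- list(
    direct_manure = factors$ef_soil_manure * applied_manure_n * N2O_PER_N,
    direct_fertilizer = factors$ef_soil_fertilizer * fert_n * N2O_PER_N,
    direct_residues = factors$ef_soil_residues * residue_n * N2O_PER_N,
    indirect_volatilization = factors$ef_volatilization * volatilized_n *
      N2O_PER_N,
    indirect_leaching = factors$ef_leaching * leached_n * N2O_PER_N,
    fertilizer_manufacture = factors$ef_fert_manufacture_n2o *
      purchased_fert_n,                       # stated directly as N2O
    purchased_forage = factors$ef_purchased_forage_n2o_n *
      purchased_forage_n * N2O_PER_N,
    purchased_concentrate = factors$ef_purchased_conc_n2o_n *
      purchased_conc_n * N2O_PER_N)
  out$total <- sum(unlist(out))
  out
}

#' Leached nitrate nitrogen
#'
#' Leached N as a drainage-driven fraction of the N applied per hectare.
#' Drainage is the annual water surplus `max(0, rainfall - ETc)`; the leached
#' fraction grows linearly with drainage (default 0.1% per mm) and is capped
#' (default 30%), so zero drainage leaches nothing.
#'
#' @param total_n_applied_kg_ha N applied (kg/ha/yr).
#' @param drainage_mm Annual drainage (mm).
#' @param factors Factor list from [ff_factors()].
#' @return kg NO3-N/ha/yr.
#' @export
leached_no3 <- function(total_n_applied_kg_ha, drainage_mm,
                        factors = ff_factors()) {
  assert_nonneg(c(total_n_applied_kg_ha, drainage_mm), "leaching inputs")
  lambda <- pmin(factors$leaching_lambda_cap,
                 factors$leaching_lambda_per_mm * drainage_mm)
  total_n_applied_kg_ha * lambda
}

#' Annual drainage from monthly climate
#'
#' @param climate 12-row climate data frame with `rainfall_mm` and `etc_mm`.
#' @return mm/yr of water surplus, `max(0, rainfall - ETc)` summed monthly.
#' @export
drainage_mm <- function(climate) {
  sum(pmax(0, climate$rainfall_mm - climate$etc_mm))
}

#' Embedded carbon dioxide of purchased inputs
#'
#' Applies the per-item CO2 factors (diesel 3.31 kg/L, electricity 0.65
#' kg/kWh, fertilizer N/P2O5/K2O 6.2/0.93/0.51 kg/kg, forage 0.2 and
#' concentrate 0.3 kg/kg, plastics 2 kg/kg, purchased animals 11 kg/kg live
#' weight, pesticides 22.2 kg/ha, milk replacer 9.73 kg/kg).  When diesel is
#' unreported the 37 L/LU/year default applies; when electricity is
#' unreported it is derived from lactating females and milking minutes.
#'
#' @param p A [purchase_ledger()].
#' @param lu Livestock units (for the diesel default).
#' @param lactating_females,milking_time_min Inputs of the electricity default.
#' @param factors Factor list from [ff_factors()].
#' @return Named list of kg CO2/yr per item plus `total`, with the resolved
#'   `diesel_L` and `electricity_kwh` as attributes.
#' @export
embedded_co2 <- function(p, lu = 0, lactating_females = 0,
                         milking_time_min = 0, factors = ff_factors()) {
  stopifnot(inherits(p, "purchase_ledger"))
  diesel_L <- if (is.na(p$diesel_L)) factors$diesel_l_per_lu * lu else
    p$diesel_L
  kwh <- if (is.na(p$electricity_kwh)) {
    factors$electricity_kwh_per_ewe_min * lactating_females * milking_time_min
  } else p$electricity_kwh
  out <- list(
    diesel = factors$co2_diesel_l * diesel_L,
    electricity = factors$co2_electricity_kwh * kwh,
    fertilizer_n = factors$co2_fert_n * p$fertilizer_n_kg,
    fertilizer_p2o5 = factors$co2_fert_p2o5 * p$fertilizer_p2o5_kg,
    fertilizer_k2o = factors$co2_fert_k2o * p$fertilizer_k2o_kg,
    forage = factors$co2_forage_kg * p$forage_kg,
    concentrate = factors$co2_concentrate_kg * p$concentrate_kg,
    peas = factors$co2_concentrate_kg * (p$peas_kg %||% 0),
    plastic = factors$co2_plastic_kg * p$plastic_kg,
    animals = factors$co2_animals_kg_lw * p$animals_liveweight_kg,
    pesticides = factors$co2_pesticides_ha * p$pesticide_treated_ha,
    milk_replacer = factors$co2_milk_replacer_kg * p$milk_replacer_kg)
  out$total <- sum(unlist(out))
  attr(out, "diesel_L") <- diesel_L
  attr(out, "electricity_kwh") <- kwh
  out
}

#' Carbon dioxide from forage conservation
#'
#' Plastic use (1.3 kg per small silo, 0.68 kg/t in bags, a default per-tonne
#' figure for round bales) at 2 kg CO2/kg plastic, plus fermentation losses
#' at 0.24 kg CO2 per kg of dry matter lost (12.3% DM loss in cereal silage,
#' 3% in maize silage).
#'
#' @param mass_t Fresh silage mass (t/yr).
#' @param method `"bag"`, `"round_bale"` or `"small_silo"`.
#' @param crop `"cereal"` or `"maize"` (selects the DM-loss rate).
#' @param dm_fraction DM content of the silage (default 0.35).
#' @param n_silos Number of small silos (for `method = "small_silo"`).
#' @param factors Factor list from [ff_factors()].
#' @return List with `plastic_co2`, `fermentation_co2`, `total` (kg CO2/yr).
#' @export
silage_co2 <- function(mass_t, method = c("bag", "round_bale", "small_silo"),
                       crop = c("cereal", "maize"), dm_fraction = 0.35,
                       n_silos = 1, factors = ff_factors()) {
  method <- match.arg(method)
  crop <- match.arg(crop)
  assert_nonneg(mass_t, "mass_t")
  plastic_kg <- switch(method,
    bag = factors$silage_plastic_bag_kg_per_t * mass_t,
    round_bale = factors$silage_plastic_round_bale_kg_per_t * mass_t,
    small_silo = factors$silage_plastic_small_silo_kg * n_silos *
      (mass_t > 0))
  loss <- if (crop == "cereal") factors$silage_dm_loss_cereal else
    factors$silage_dm_loss_maize
  ferment <- 1000 * mass_t * dm_fraction * loss *
    factors$silage_co2_per_kg_dm_lost
  list(plastic_co2 = factors$co2_plastic_kg * plastic_kg,
       fermentation_co2 = ferment,
       total = factors$co2_plastic_kg * plastic_kg + ferment)
}

#' Soil carbon sequestration
#'
#' Carbon entering the soil as plant residues (45% C of residue dry matter)
#' and as manure (13.4 kg C per kg manure N), times a humification
#' coefficient (default 0.1), expressed as removed CO2 (x 44/12).  Enters the
#' ledger as a negative CO2 mass in the `sequestration` category.
#'
#' @param residue_dm_kg Plant residue dry matter reaching the soil (kg/yr).
#' @param manure_n_kg N in manure applied to the farm's soils (kg/yr).
#' @param humification Fraction of incoming C stabilized, in [0, 1].
#' @param factors Factor list from [ff_factors()].
#' @return kg CO2/yr (positive magnitude of the removal).
#' @export
carbon_sequestration <- function(residue_dm_kg, manure_n_kg = 0,
                                 humification = NULL,
                                 factors = ff_factors()) {
  assert_nonneg(c(residue_dm_kg, manure_n_kg), "sequestration inputs")
  if (is.null(humification)) humification <- factors$humification
  assert_fraction(humification, "humification")
  c_in <- factors$biomass_carbon_fraction * residue_dm_kg +
    factors$manure_c_to_n * manure_n_kg
  humification * c_in * 44 / 12
}

#' Carbon dioxide equivalents of a ledger
#'
#' Applies the global-warming potentials 1 (CO2), 28 (CH4) and 298 (N2O),
#' preserving the sign of sequestration entries.
#'
#' @param led An [emission_ledger()].
#' @param factors Factor list from [ff_factors()].
#' @return List with `total` (kg CO2e/yr) and `by_category` (named vector).
#' @export
co2e <- function(led, factors = ff_factors()) {
  validate_ledger(led)
  gwp <- c(CO2 = 1, CH4 = factors$gwp_ch4, N2O = factors$gwp_n2o)
  if (!nrow(led)) return(list(total = 0, by_category = numeric()))
  w <- led$kg * gwp[led$gas]
  by_cat <- tapply(w, led$category, sum)
  list(total = sum(w), by_category = c(by_cat))
}
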