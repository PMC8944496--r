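#' Fat- and protein-corrected milk
#'
#' Normalizes milk volume to the reference composition of 6.5% fat and 5.8%
#' protein with `L x (0.25 + 0.085 x fat + 0.035 x protein)`; the default
#' coefficients give a correction factor of ~1 (1.0055) at the reference
#' composition and are configurable.
#'
#' @param liters Milk volume (L).
#' @param fat_pct,protein_pct Milk composition (%).
#' @param factors Factor list from [ff_factors()].
#' @return L of FPCM.
#' @export
fpcm <- function(liters, fat_pct, protein_pct, factors = ff_factors()) {
  assert_nonneg(liters, "liters")
  liters * (factors$fpcm_base + factors$fpcm_fat * fat_pct +
              factors$fpcm_protein * protein_pct)
}

#' Milk/meat emission allocation
#'
#' Allocation factor of total emissions to milk: `AF = 1 - 5.7717 R`, where
#' `R` is the mass of meat (live weight sold per hectare) over the mass of
#' milk sold per hectare, clamped into [0, 1].  Meat receives `1 - AF`.
#' Meat-only farms (zero milk) are outside the model's scope.
#'
#' @param m_meat_kg_ha,m_milk_kg_ha Product masses (kg/ha/yr).
#' @param factors Factor list from [ff_factors()].
#' @return List with `R` and `AF`.
#' @examples
#' allocation_factor(85.7, 1500)  # AF ~0.67
#' @export
allocation_factor <- function(m_meat_kg_ha, m_milk_kg_ha,
                              factors = ff_factors()) {
  assert_nonneg(m_meat_kg_ha, "m_meat_kg_ha")
  if (!is.finite(m_milk_kg_ha) || m_milk_kg_ha <= 0) {
    stop("allocation undefined for zero milk (meat-only farm unsupported)",
         call. = FALSE)
  }
  r <- m_meat_kg_ha / m_milk_kg_ha
  list(R = r, AF = min(1, max(0, 1 - factors$allocation_slope * r)))
}

#' Carbon footprint over the four functional units
#'
#' The partial carbon footprint (PCF) is the CO2e sum of all on- and off-farm
#' pathways in the ledger except the soybean, indirect land-use-change and
#' sequestration add-ons; the total carbon footprint is
#' `TCF = PCF + SY + iLUC - CS`.  Per-FU values divide by hectares, livestock
#' units, present females, and liters of FPCM; the per-liter figure carries
#' the milk allocation factor, while per-ha/LU/female report the unallocated
#' total (milk and meat leave the same farm).
#'
#' @param led An [emission_ledger()] containing all pathway entries,
#'   including `soybean`, `iLUC` and (negative) `sequestration` categories
#'   where applicable.
#' @param area_ha,lu,pf Denominators: farmland, livestock units, present
#'   females.
#' @param fpcm_L Fat- and protein-corrected milk (L/yr), > 0 for the
#'   per-liter unit (otherwise that entry is `NA`).
#' @param af Milk allocation factor from [allocation_factor()] (default 1).
#' @param factors Factor list from [ff_factors()].
#' @return List of class `carbon_footprint`: `pcf_kg_co2e`, `tcf_kg_co2e`,
#'   `sy`, `iluc`, `cs`, `af`, and `per_fu` (named vector over
#'   `ha`, `LU`, `present_female`, `L_FPCM`).
#' @export
carbon_footprint <- function(led, area_ha, lu, pf, fpcm_L, af = 1,
                             factors = ff_factors()) {
  cz <- co2e(led, factors)
  by_cat <- cz$by_category
  pick <- function(cat) if (cat %in% names(by_cat)) by_cat[[cat]] else 0
  sy <- pick("soybean")
  iluc <- pick("iLUC")
  cs <- -pick("sequestration")            # stored negative, report magnitude
  pcf <- cz$total - sy - iluc + cs
  tcf <- pcf + sy + iluc - cs             # = cz$total, kept explicit
  per_fu <- c(
    ha = if (area_ha > 0) tcf / area_ha else NA_real_,
    LU = if (lu > 0) tcf / lu else NA_real_,
    present_female = if (pf > 0) tcf / pf else NA_real_,
    L_FPCM = if (fpcm_L > 0) af * tcf / fpcm_L else NA_real_)
  structure(list(pcf_kg_co2e = pcf, tcf_kg_co2e = tcf, sy = sy, iluc = iluc,
                 cs = cs, af = af, per_fu = per_fu),
            class = "carbon_footprint")
}

#' Acidification and eutrophication potentials
#'
#' Ap in SO2 equivalents (SO2 x 1, NOx x 0.7, NH3 x 1.89) and Ep in NO3
#' equivalents (NO3 x 1, NOx x 1.35, NH3 x 3.64, PO4 x 10.45).
#'
#' @param so2_kg,nox_kg,nh3_kg,no3_kg,po4_kg Emitted masses (kg/yr).
#' @param factors Factor list from [ff_factors()].
#' @return List with `ap_kg_so2e` and `ep_kg_no3e`.
#' @export
impact_potentials <- function(so2_kg = 0, nox_kg = 0, nh3_kg = 0,
                              no3_kg = 0, po4_kg = 0, factors = ff_factors()) {
  assert_nonneg(c(so2_kg, nox_kg, nh3_kg, no3_kg, po4_kg), "impact masses")
  list(ap_kg_so2e = factors$ap_so2 * so2_kg + factors$ap_nox * nox_kg +
         factors$ap_nh3 * nh3_kg,
       ep_kg_no3e = factors$ep_no3 * no3_kg + factors$ep_nox * nox_kg +
         factors$ep_nh3 * nh3_kg + factors$ep_po4 * po4_kg)
}

#' Water, energy and nitrogen footprints
#'
#' Water: green/blue/grey of on-farm crops (from monthly ETc and rainfall)
#' and of imported products (per-product table), plus drinking water
#' (per-head default) and cleaning water at 2.2 L per liter of milk.  The
#' partial water footprint (WFp) is blue + grey.  Energy: direct (diesel +
#' electricity energy densities) plus indirect (per-item MJ factors).
#' Nitrogen: NFt is the sum of all imported N; NFr adds up the emitted
#' reactive species (NH3, N2O-N, NO, N2, NO3).
#'
#' @param farm A [farm_config()].
#' @param imports Named list of imported product masses (kg/yr) keyed by the
#'   products of [ff_water_energy_table()].
#' @param milk_L Milk produced (L/yr) for cleaning water.
#' @param heads Animals present (for drinking water).
#' @param diesel_L,electricity_kwh Resolved energy purchases.
#' @param n_imported_kg Total imported N (kg/yr) for NFt.
#' @param reactive_n_kg Named vector of emitted reactive N species masses
#'   (kg N/yr) for NFr.
#' @param factors Factor list from [ff_factors()].
#' @param we_table Per-product water/energy factors.
#' @return List with `wf` (green, blue, grey, drinking, cleaning, partial,
#'   total; m3/yr), `ef` (direct, indirect, total; MJ/yr), `nf_total_kg`,
#'   `nf_reactive_kg`.
#' @export
water_energy_n_footprints <- function(farm, imports = list(), milk_L = 0,
                                      heads = 0, diesel_L = 0,
                                      electricity_kwh = 0,
                                      n_imported_kg = 0,
                                      reactive_n_kg = numeric(),
                                      factors = ff_factors(),
                                      we_table = ff_water_energy_table()) {
  # on-farm crop water: green = min(rain, ETc); blue = irrigation gap
  green <- blue <- 0
  if (nrow(farm$land)) {
    cropped <- sum(farm$land$area_ha[farm$land$crop != "fallow"])
    etc <- farm$climate$etc_mm
    rain <- farm$climate$rainfall_mm
    green <- sum(pmin(rain, etc)) * cropped * 10      # 1 mm over 1 ha = 10 m3
    blue <- sum(pmax(0, etc - rain)) * cropped * 10
  }
  grey <- 0
  imp_w <- c(green = 0, blue = 0, grey = 0)
  imp_e <- 0
  for (prod in names(imports)) {
    row <- we_table[we_table$product == prod, ]
    if (!nrow(row)) {
      stop("no water/energy factors for product: ", prod, call. = FALSE)
    }
    t <- imports[[prod]] / 1000
    imp_w <- imp_w + c(green = row$water_green_m3_t * t,
                       blue = row$water_blue_m3_t * t,
                       grey = row$water_grey_m3_t * t)
    imp_e <- imp_e + row$energy_mj_kg * imports[[prod]]
  }
  drinking <- factors$drinking_water_l_per_head_day * heads * 365 / 1000
  cleaning <- factors$cleaning_water_l_per_l_milk * milk_L / 1000
  wf_green <- green + unname(imp_w["green"])
  wf_blue <- blue + unname(imp_w["blue"]) + drinking + cleaning
  wf_grey <- grey + unname(imp_w["grey"])
  ef_direct <- factors$diesel_mj_per_l * diesel_L +
    factors$electricity_mj_per_kwh * electricity_kwh
  list(wf = list(green = wf_green, blue = wf_blue, grey = wf_grey,
                 drinking = drinking, cleaning = cleaning,
                 partial = wf_blue + wf_grey,
                 total = wf_green + wf_blue + wf_grey),
       ef = list(direct = ef_direct, indirect = imp_e,
                 total = ef_direct + imp_e),
       nf_total_kg = n_imported_kg,
       nf_reactive_kg = sum(reactive_n_kg))
}

#' Land use per liter of corrected milk
#'
#' Off-farm area supporting purchased feed uses the shipped reference yields
#' (t/ha) per product; on-farm area is the farm's own cropped land.  Results
#' are m2 per liter of FPCM.
#'
#' @param off_farm_feed_kg Named list/vector of purchased feed (kg/yr) keyed
#'   by products of [ff_yield_table()].
#' @param on_farm_area_m2 On-farm feed-producing area (m2).
#' @param fpcm_L FPCM (L/yr), > 0.
#' @param yield_table Reference yields.
#' @return List with `on_m2_per_l`, `off_m2_per_l`, `total_m2_per_l`,
#'   `off_farm_m2`.
#' @export
land_use <- function(off_farm_feed_kg = list(), on_farm_area_m2 = 0,
                     fpcm_L, yield_table = ff_yield_table()) {
  if (!is.finite(fpcm_L) || fpcm_L <= 0) {
    stop("fpcm_L must be > 0", call. = FALSE)
  }
  off_m2 <- 0
  for (prod in names(off_farm_feed_kg)) {
    y <- yield_table$yield_t_ha[yield_table$product == prod]
    if (!length(y)) stop("no reference yield for product: ", prod,
                         call. = FALSE)
    off_m2 <- off_m2 + off_farm_feed_kg[[prod]] / (y * 1000) * 10000
  }
  list(on_m2_per_l = on_farm_area_m2 / fpcm_L,
       off_m2_per_l = off_m2 / fpcm_L,
       total_m2_per_l = (on_farm_area_m2 + off_m2) / fpcm_L,
       off_farm_m2 = off_m2)
}
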