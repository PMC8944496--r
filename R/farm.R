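#' Describe one farm-year
#'
#' A `farm_config` holds the complete description of one dairy sheep or goat
#' farm over a single year: land base and crops, herd inventory, purchased
#' inputs, grazing schedule, milk volume and composition, and monthly climate.
#' It is the single input to the whole-farm simulator.
#'
#' @param breed_group One of `"Manchega"`, `"Foreigners"` (Lacaune/Assaf) or
#'   `"Florida"` (goats).
#' @param land A data frame of parcels as built by [land_parcel()] (rows can be
#'   combined with `rbind`); may have zero rows for landless systems.
#' @param communal_pasture_ha Communal pasture area (ha).
#' @param herd A [herd_inventory()].
#' @param purchases A [purchase_ledger()].
#' @param grazing_time_fraction Fraction of the year spent grazing, in [0, 1].
#' @param milking_time_min Daily milking-parlor time (minutes).
#' @param milk_sold_L Marketed milk (liters/year).
#' @param milk_fat_pct,milk_protein_pct Milk composition (%).
#' @param live_weight_sold_kg Live weight sold (kg/year).
#' @param manure_sold_kg Manure sold off-farm (kg fresh/year).
#' @param bedding_straw_kg_per_female Bedding straw use (kg/female/year);
#'   the survey default is 225.
#' @param climate A data frame of 12 monthly records from [climate_month()].
#' @return An object of class `farm_config`.
#' @seealso [validate_farm()], [simulate_farm()], [gen_farm()]
#' @export
farm_config <- function(breed_group,
                        land = land_parcel()[0, ],
                        communal_pasture_ha = 0,
                        herd = herd_inventory(),
                        purchases = purchase_ledger(),
                        grazing_time_fraction = 0,
                        milking_time_min = 120,
                        milk_sold_L = 0,
                        milk_fat_pct = 6.5,
                        milk_protein_pct = 5.8,
                        live_weight_sold_kg = 0,
                        manure_sold_kg = 0,
                        bedding_straw_kg_per_female = 225,
                        climate = gen_climate(seed = 1L)) {
  breed_group <- match.arg(breed_group, c("Manchega", "Foreigners", "Florida"))
  farm <- structure(
    list(breed_group = breed_group,
         land = land,
         communal_pasture_ha = communal_pasture_ha,
         herd = herd,
         purchases = purchases,
         grazing_time_fraction = grazing_time_fraction,
         milking_time_min = milking_time_min,
         milk_sold_L = milk_sold_L,
         milk_fat_pct = milk_fat_pct,
         milk_protein_pct = milk_protein_pct,
         live_weight_sold_kg = live_weight_sold_kg,
         manure_sold_kg = manure_sold_kg,
         bedding_straw_kg_per_female = bedding_straw_kg_per_female,
         climate = climate),
    class = "farm_config")
  validate_farm(farm)
  farm
}

FF_CROPS <- c("barley_grain", "oats_forage", "triticale_forage", "vetch_oat",
              "maize_silage", "alfalfa", "legumes", "fallow")
FF_USES  <- c("hay", "silage_bag", "silage_round_bale", "grazing", "grain")

#' Land parcels
#'
#' One row per crop block: crop, area, expected dry-matter yield, intended
#' use (hay, silage, grazing, grain) and fertilization.
#'
#' @param crop Crop identifier (see `flockfoot:::FF_CROPS`).
#' @param area_ha Area (ha).
#' @param yield_t_dm_ha Expected yield (t DM/ha).
#' @param use Intended use of the harvest.
#' @param fert_n,fert_p,fert_k Fertilizer applied (kg/ha of N, P2O5, K2O).
#' @return A data frame with one row per parcel.
#' @export
land_parcel <- function(crop = character(), area_ha = numeric(),
                        yield_t_dm_ha = 0, use = "hay",
                        fert_n = 0, fert_p = 0, fert_k = 0) {
  if (length(crop)) {
    crop <- match.arg(crop, FF_CROPS, several.ok = TRUE)
    use <- match.arg(use, FF_USES, several.ok = TRUE)
    assert_nonneg(area_ha, "area_ha")
    assert_nonneg(yield_t_dm_ha, "yield_t_dm_ha")
  }
  data.frame(crop = crop, area_ha = area_ha, yield_t_dm_ha = yield_t_dm_ha,
             use = if (length(crop)) use else character(),
             fert_n = if (length(crop)) fert_n else numeric(),
             fert_p = if (length(crop)) fert_p else numeric(),
             fert_k = if (length(crop)) fert_k else numeric(),
             stringsAsFactors = FALSE)
}

FF_HERD_CLASSES <- c("lactating_high", "lactating_medium", "lactating_low",
                     "non_lactating", "replacement_0_4", "replacement_4_12",
                     "studs", "offspring")

#' Herd inventory
#'
#' Animal counts by production class, mean live weights, and the flock's
#' genetic value index used by the milk-per-lactation model.
#'
#' @param lactating_high,lactating_medium,lactating_low Lactating females by
#'   production lot.
#' @param non_lactating Dry and pregnant females.
#' @param replacement_0_4,replacement_4_12 Replacement females by age (months).
#' @param studs Breeding males.
#' @param offspring Suckling lambs/kids present.
#' @param live_weight_kg Named vector of mean live weight (kg) per class;
#'   classes not named fall back to the adult default.
#' @param genetic_value Flock genetic value index (national scheme scale).
#' @return An object of class `herd_inventory`.
#' @export
herd_inventory <- function(lactating_high = 0, lactating_medium = 0,
                           lactating_low = 0, non_lactating = 0,
                           replacement_0_4 = 0, replacement_4_12 = 0,
                           studs = 0, offspring = 0,
                           live_weight_kg = c(adult = 70),
                           genetic_value = 0) {
  counts <- c(lactating_high = lactating_high,
              lactating_medium = lactating_medium,
              lactating_low = lactating_low,
              non_lactating = non_lactating,
              replacement_0_4 = replacement_0_4,
              replacement_4_12 = replacement_4_12,
              studs = studs, offspring = offspring)
  assert_nonneg(counts, "herd counts")
  structure(list(counts = counts,
                 live_weight_kg = live_weight_kg,
                 genetic_value = genetic_value),
            class = "herd_inventory")
}

#' @rdname herd_inventory
#' @param herd A `herd_inventory`.
#' @details `present_females()` counts the breeding females present (lactating
#'   plus dry), the independent variable of the herd-demography models.
#' @export
present_females <- function(herd) {
  unname(sum(herd$counts[c("lactating_high", "lactating_medium",
                           "lactating_low", "non_lactating")]))
}

#' Purchased inputs for one farm-year
#'
#' @param forage_kg,concentrate_kg,soybean_kg Purchased feed (kg/yr; soybean is
#'   tracked separately because it carries its own embedded and land-use-change
#'   emissions).
#' @param fertilizer_n_kg,fertilizer_p2o5_kg,fertilizer_k2o_kg Mineral
#'   fertilizer (kg/yr of N, P2O5, K2O).
#' @param diesel_L Diesel (L/yr); `NA` lets the simulator apply the 37
#'   L/LU/year default.
#' @param electricity_kwh Electricity (kWh/yr); `NA` derives it from lactating
#'   females and milking time.
#' @param plastic_kg Silage/other plastics (kg/yr).
#' @param animals_liveweight_kg Purchased animals (kg live weight/yr).
#' @param pesticide_treated_ha Pesticide-treated area (ha/yr).
#' @param milk_replacer_kg Milk replacer powder (kg/yr).
#' @return An object of class `purchase_ledger`.
#' @export
purchase_ledger <- function(forage_kg = 0, concentrate_kg = 0, soybean_kg = 0,
                            fertilizer_n_kg = 0, fertilizer_p2o5_kg = 0,
                            fertilizer_k2o_kg = 0, diesel_L = NA_real_,
                            electricity_kwh = NA_real_, plastic_kg = 0,
                            animals_liveweight_kg = 0, pesticide_treated_ha = 0,
                            milk_replacer_kg = 0, peas_kg = 0) {
  out <- list(forage_kg = forage_kg, concentrate_kg = concentrate_kg,
              soybean_kg = soybean_kg, peas_kg = peas_kg,
              fertilizer_n_kg = fertilizer_n_kg,
              fertilizer_p2o5_kg = fertilizer_p2o5_kg,
              fertilizer_k2o_kg = fertilizer_k2o_kg, diesel_L = diesel_L,
              electricity_kwh = electricity_kwh, plastic_kg = plastic_kg,
              animals_liveweight_kg = animals_liveweight_kg,
              pesticide_treated_ha = pesticide_treated_ha,
              milk_replacer_kg = milk_replacer_kg)
  known <- unlist(out[!is.na(unlist(out))])
  assert_nonneg(known, "purchase quantities")
  structure(out, class = "purchase_ledger")
}

#' Monthly climate record
#'
#' @param month Month number 1-12.
#' @param t_max,t_min Mean daily maximum/minimum temperature (deg C).
#' @param rainfall_mm Monthly rainfall (mm).
#' @param relative_humidity_pct Mean relative humidity (%).
#' @param etc_mm Crop evapotranspiration ETc (mm), computed externally
#'   (e.g. with CROPWAT) and supplied as an input.
#' @return A data frame, one row per month.
#' @export
climate_month <- function(month, t_max, t_min, rainfall_mm,
                          relative_humidity_pct = 60, etc_mm = 0) {
  if (any(t_max < t_min)) stop("t_max must be >= t_min", call. = FALSE)
  assert_nonneg(rainfall_mm, "rainfall_mm")
  data.frame(month = month, t_max = t_max, t_min = t_min,
             rainfall_mm = rainfall_mm,
             relative_humidity_pct = relative_humidity_pct,
             etc_mm = etc_mm)
}

#' Structural validation of a farm configuration
#'
#' Rejects negative masses/areas/counts, grazing fractions outside [0, 1],
#' implausible milk composition, and lactating totals exceeding the present
#' females.  Called by [farm_config()] and again by [simulate_farm()] so that
#' hand-edited configs read from YAML are checked too.
#'
#' @param farm A [farm_config()].
#' @return The farm, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_farm <- function(farm) {
  stopifnot(inherits(farm, "farm_config"))
  assert_fraction(farm$grazing_time_fraction, "grazing_time_fraction")
  assert_nonneg(farm$communal_pasture_ha, "communal_pasture_ha")
  assert_nonneg(farm$milking_time_min, "milking_time_min")
  assert_nonneg(farm$milk_sold_L, "milk_sold_L")
  assert_nonneg(farm$live_weight_sold_kg, "live_weight_sold_kg")
  assert_nonneg(farm$manure_sold_kg, "manure_sold_kg")
  assert_nonneg(farm$bedding_straw_kg_per_female, "bedding_straw_kg_per_female")
  assert_fraction(farm$milk_fat_pct, "milk_fat_pct", 0 + 1e-9, 15 - 1e-9)
  assert_fraction(farm$milk_protein_pct, "milk_protein_pct", 0 + 1e-9, 15 - 1e-9)
  if (nrow(farm$land)) {
    assert_nonneg(farm$land$area_ha, "land$area_ha")
    assert_nonneg(farm$land$yield_t_dm_ha, "land$yield_t_dm_ha")
  }
  h <- farm$herd
  lact <- sum(h$counts[c("lactating_high", "lactating_medium", "lactating_low")])
  if (lact > present_females(h) + 1e-9) {
    stop("lactating subtotal exceeds present females", call. = FALSE)
  }
  if (nrow(farm$climate) != 12) {
    stop("climate must contain 12 monthly records", call. = FALSE)
  }
  invisible(farm)
}

#' Livestock units and stocking density
#'
#' Converts a herd inventory to livestock units (LU) with per-class
#' coefficients and expresses the stocking level per hectare.  The LU
#' conversion coefficients are not universal; the shipped defaults (adult
#' 0.15, replacement 0.09, lamb/kid 0.05) can be replaced via `lu_table`.
#'
#' @param herd A [herd_inventory()].
#' @param lu_table Data frame `class, coefficient` ([ff_lu_table()] default).
#' @return Total livestock units (numeric scalar).
#' @examples
#' h <- herd_inventory(lactating_high = 100)
#' livestock_units(h)  # 100 x 0.15 = 15
#' @export
livestock_units <- function(herd, lu_table = ff_lu_table()) {
  counts <- herd$counts
  populated <- names(counts)[counts > 0]
  missing <- setdiff(populated, lu_table$class)
  if (length(missing)) {
    stop("no LU coefficient for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  coefs <- lu_table$coefficient[match(names(counts), lu_table$class)]
  coefs[is.na(coefs)] <- 0
  sum(counts * coefs)
}

#' @rdname livestock_units
#' @param lu Livestock units.
#' @param area_ha Reference land area (ha); must be > 0.
#' @return `stocking_density()`: LU per hectare.
#' @export
stocking_density <- function(lu, area_ha) {
  assert_nonneg(lu, "lu")
  if (!is.finite(area_ha) || area_ha <= 0) {
    stop("stocking density undefined: area_ha must be > 0", call. = FALSE)
  }
  lu / area_ha
}

#' Total farmland of a configuration
#'
#' Arable parcels plus communal pasture; the per-hectare denominator used by
#' balances and footprints.
#' @param farm A [farm_config()].
#' @return Area in hectares.
#' @export
farm_area_ha <- function(farm) {
  sum(farm$land$area_ha) + farm$communal_pasture_ha
}

#' Read and write farm configurations as YAML
#'
#' The on-disk format mirrors the `farm_config` structure with plain lists;
#' land and climate blocks are lists of records.
#'
#' @param path File path.
#' @param farm A [farm_config()].
#' @return `read_farm_config()` returns a validated `farm_config`.
#' @export
read_farm_config <- function(path) {
  if (!file.exists(path)) stop("farm config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  needed <- c("breed_group", "herd")
  miss <- setdiff(needed, names(y))
  if (length(miss)) {
    stop("farm config '", path, "' missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  land <- if (is.null(y$land) || !length(y$land)) land_parcel()[0, ] else
    do.call(rbind, lapply(y$land, function(p) do.call(land_parcel, p)))
  climate <- if (is.null(y$climate)) gen_climate(seed = 1L) else
    do.call(rbind, lapply(y$climate, function(m) do.call(climate_month, m)))
  herd <- do.call(herd_inventory, y$herd)
  purchases <- if (is.null(y$purchases)) purchase_ledger() else
    do.call(purchase_ledger, y$purchases)
  scal <- y[setdiff(names(y), c("land", "climate", "herd", "purchases"))]
  do.call(farm_config, c(scal, list(land = land, climate = climate,
                                    herd = herd, purchases = purchases)))
}

#' @rdname read_farm_config
#' @export
write_farm_config <- function(farm, path) {
  y <- list(breed_group = farm$breed_group,
            communal_pasture_ha = farm$communal_pasture_ha,
            grazing_time_fraction = farm$grazing_time_fraction,
            milking_time_min = farm$milking_time_min,
            milk_sold_L = farm$milk_sold_L,
            milk_fat_pct = farm$milk_fat_pct,
            milk_protein_pct = farm$milk_protein_pct,
            live_weight_sold_kg = farm$live_weight_sold_kg,
            manure_sold_kg = farm$manure_sold_kg,
            bedding_straw_kg_per_female = farm$bedding_straw_kg_per_female,
            herd = c(as.list(farm$herd$counts),
                     list(live_weight_kg = farm$herd$live_weight_kg,
                          genetic_value = farm$herd$genetic_value)),
            purchases = unclass(farm$purchases),
            land = lapply(seq_len(nrow(farm$land)),
                          function(i) as.list(farm$land[i, ])),
            climate = lapply(seq_len(nrow(farm$climate)),
                             function(i) as.list(farm$climate[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}
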