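#' Feedstuffs and rations
#'
#' A `feedstuff` is one row of composition (fractions of DM unless noted); a
#' `ration` is a set of feedstuffs with daily allowances for one animal class.
#' Compositions ship in `inst/extdata/feed_composition.csv` and can be looked
#' up by name with `feedstuff()`.
#'
#' @param name Feed name; when `composition` is `NULL`, looked up in the
#'   shipped composition table.
#' @param composition Optional named list overriding/defining the composition
#'   (`dm`, `cp`, `ndf`, `adf`, `omd`, `starch`, `ee`, `ne_mcal_kg`, `n`, `p`).
#' @param feed_table Composition table from [ff_feed_table()].
#' @return A one-row data frame of class `feedstuff`.
#' @export
feedstuff <- function(name, composition = NULL, feed_table = ff_feed_table()) {
  if (is.null(composition)) {
    row <- feed_table[feed_table$name == name, ]
    if (!nrow(row)) {
      stop("feedstuff not in composition table: ", name, call. = FALSE)
    }
  } else {
    row <- as.data.frame(c(list(name = name), composition))
  }
  fracs <- intersect(c("dm", "cp", "ndf", "adf", "omd", "starch", "ee", "n", "p"),
                     names(row))
  for (f in fracs) assert_fraction(row[[f]], paste0("feed ", name, " $", f))
  class(row) <- c("feedstuff", "data.frame")
  row
}

#' @rdname feedstuff
#' @param components Named numeric vector: kg DM/head/day per feed name.
#' @param animal_class Herd class the ration is fed to.
#' @param grazing_km_per_day Distance walked while grazing (km/day).
#' @param grazing_hours Grazing time (h/day).
#' @return `ration()`: an object of class `ration`.
#' @export
ration <- function(components, animal_class = "lactating_medium",
                   grazing_km_per_day = 0, grazing_hours = 0,
                   feed_table = ff_feed_table()) {
  if (!length(components)) stop("empty ration", call. = FALSE)
  assert_nonneg(components, "ration amounts")
  feeds <- do.call(rbind, lapply(names(components), feedstuff,
                                 feed_table = feed_table))
  structure(list(feeds = feeds, kg_dm = unname(components),
                 animal_class = animal_class,
                 grazing_km_per_day = grazing_km_per_day,
                 grazing_hours = grazing_hours),
            class = "ration")
}

#' Daily nutrient totals of a ration
#'
#' Mass-weighted sums per head and day: dry-matter intake, N, crude (gross)
#' protein, NDF, gross and net energy, P; OMD is the DM-weighted mean.  These
#' totals are the inputs of the excreta regressions and of enteric methane.
#'
#' @param r A [ration()].
#' @param ge_mj_per_kg Gross energy density of DM (MJ/kg), default 18.55.
#' @return List with `dmi_g`, `n_g`, `gp_g`, `ndf_g`, `omd_weighted`,
#'   `ge_mj`, `ne_mcal`, `p_g`.
#' @export
ration_totals <- function(r, ge_mj_per_kg = 18.55) {
  stopifnot(inherits(r, "ration"))
  kg <- r$kg_dm
  f <- r$feeds
  dmi_g <- 1000 * sum(kg)
  if (dmi_g == 0) stop("ration has zero intake", call. = FALSE)
  list(dmi_g = dmi_g,
       n_g = 1000 * sum(kg * f$n),
       gp_g = 1000 * sum(kg * f$cp),
       ndf_g = 1000 * sum(kg * f$ndf),
       omd_weighted = sum(kg * f$omd) / sum(kg),
       ge_mj = sum(kg) * ge_mj_per_kg,
       ne_mcal = sum(kg * f$ne_mcal_kg),
       p_g = 1000 * sum(kg * f$p))
}

#' Potential milk production from energy intake
#'
#' Net energy intake minus maintenance (including grazing activity), divided
#' by the net energy cost of one liter of milk; clamped at zero when intake
#' does not cover maintenance.
#'
#' @param nei_mcal Net energy intake (Mcal/head/day).
#' @param nem_mcal Maintenance net energy (Mcal/head/day).
#' @param energy_per_liter_mcal Net energy per liter of milk (Mcal/L), > 0.
#' @return Liters/head/day.
#' @export
potential_milk <- function(nei_mcal, nem_mcal, energy_per_liter_mcal) {
  if (!is.finite(energy_per_liter_mcal) || energy_per_liter_mcal <= 0) {
    stop("energy_per_liter_mcal must be > 0", call. = FALSE)
  }
  if (nei_mcal < nem_mcal) {
    warning("net energy intake below maintenance; potential milk clamped to 0",
            call. = FALSE)
  }
  max(0, nei_mcal - nem_mcal) / energy_per_liter_mcal
}

#' Potential milk protein from metabolizable protein intake
#'
#' Applies the free-amino-acid assimilation rates into milk protein:
#' 58% in sheep and 68% in goats, after deducting the maintenance
#' metabolizable protein requirement.
#'
#' @param mp_intake_g Metabolizable protein intake (g/head/day).
#' @param species `"sheep"` or `"goat"`.
#' @param mp_maint_g Maintenance MP requirement (g/head/day), default 0.
#' @return g milk protein/head/day.
#' @export
potential_milk_protein <- function(mp_intake_g, species = c("sheep", "goat"),
                                   mp_maint_g = 0) {
  species <- match.arg(species)
  assert_nonneg(mp_intake_g, "mp_intake_g")
  rate <- if (species == "sheep") 0.58 else 0.68
  max(0, mp_intake_g - mp_maint_g) * rate
}

#' Nitrogen and phosphorus use efficiency of the diet
#'
#' Share of ingested N (and P) recovered in milk plus meat, in percent.
#' Values above 100 are physically impossible over a year and trigger a
#' balance warning rather than an error, so bookkeeping slips surface
#' without aborting a run.
#'
#' @param n_milk,n_meat,n_intake N in milk, meat, and intake (same units).
#' @param p_milk,p_meat,p_intake P analogues.
#' @return List with `nue_pct` and `pue_pct`.
#' @export
nue_pue <- function(n_milk, n_meat, n_intake, p_milk, p_meat, p_intake) {
  if (n_intake <= 0 || p_intake <= 0) {
    stop("efficiency undefined: intake must be > 0", call. = FALSE)
  }
  nue <- 100 * (n_milk + n_meat) / n_intake
  pue <- 100 * (p_milk + p_meat) / p_intake
  if (nue > 100 || pue > 100) {
    warning("nutrient output exceeds intake (NUE/PUE > 100%): check balances",
            call. = FALSE)
  }
  list(nue_pct = nue, pue_pct = pue)
}
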