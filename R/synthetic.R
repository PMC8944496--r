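# Truncated-normal draw by rejection below `lower`; several survey fields
# have sd > mean, so plain normals would go negative.
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (!is.finite(mean) || !is.finite(sd)) stop("bad moments", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
    guard <- guard + 1
    if (guard > 1000) {                      # pathological mean << 0
      out[bad] <- lower
      break
    }
  }
  out
}

# Mean-preserving truncated normal: shifts the location parameter so the
# truncated distribution keeps the target mean.  For fields with sd > mean
# this pushes location below zero, giving the observed pile-up near zero
# (zero-inflation-like) while the long-run average still matches the survey.
rtruncnorm_m <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  tn_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  if (tn_mean(mean - 6 * sd) >= mean) {
    mu <- mean                              # truncation negligible
  } else {
    mu <- stats::uniroot(function(m) tn_mean(m) - mean,
                         c(mean - 6 * sd, mean + sd))$root
  }
  rtruncnorm(n, mu, sd, lower)
}

#' Generate a synthetic farm
#'
#' Draws one internally consistent farm-year from the survey's per-breed
#' means and standard deviations (truncated normal, rejecting negatives):
#' land areas, herd counts, purchases, grazing time, milk yield and
#' composition, live weight sold, fertilization, climate.  Herd subclasses
#' are rescaled after sampling so lactating females never exceed adults, and
#' the lactating lot is split 46/29/25% into high/medium/low production
#' (the surveyed distribution).  Deterministic for a given seed.
#'
#' @param seed Integer RNG seed.
#' @param breed_group `"Manchega"`, `"Foreigners"` or `"Florida"`.
#' @param moments Survey moment table from [ff_survey_moments()].
#' @param genetic_value Flock genetic value index (default 9, a mid-scheme
#'   value; the survey's per-farm indices are not public).
#' @return A validated [farm_config()].
#' @export
gen_farm <- function(seed, breed_group = c("Manchega", "Foreigners", "Florida"),
                     moments = ff_survey_moments(), genetic_value = 9) {
  breed_group <- match.arg(breed_group)
  m <- moments[moments$breed_group == breed_group, ]
  par <- function(f) {
    row <- m[m$field == f, ]
    if (!nrow(row)) stop("no survey moments for field ", f, call. = FALSE)
    row
  }
  set.seed(seed)
  draw <- function(f) {
    r <- par(f)
    rtruncnorm_m(1, r$mean, r$sd)
  }

  total_ha <- draw("total_ha")
  arable <- min(draw("arable_ha"), total_ha)
  communal <- max(0, total_ha - arable)
  fallow <- min(draw("fallow_ha"), arable)
  grain <- draw("cereal_grain_ha")
  forage <- draw("cereal_forage_ha")
  maize <- draw("maize_ha")
  legumes <- draw("legumes_ha")
  # rescale cropped blocks into the arable area net of fallow
  cropped <- grain + forage + maize + legumes
  avail <- max(arable - fallow, 0)
  if (cropped > avail && cropped > 0) {
    k <- avail / cropped
    grain <- grain * k; forage <- forage * k
    maize <- maize * k; legumes <- legumes * k
  }

  animals <- round(draw("animals_total"))
  lact <- draw("lactating")
  repl <- draw("replacement")
  # joint rescale so lactating + replacement leave room for dry females
  # (survey: lactating are ~62% of adults, never the whole census)
  if (lact + repl > 0.85 * animals) {
    k <- 0.85 * animals / (lact + repl)
    lact <- lact * k
    repl <- repl * k
  }
  lact <- round(lact)
  repl <- round(repl)
  adults_dry <- max(animals - lact - repl, 0)
  lact_split <- round(lact * c(0.46, 0.29, 0.25))
  lact_split[1] <- lact - sum(lact_split[-1])
  offspring_rate <- 1.91                     # born per present female
  pf <- lact + adults_dry
  offspring <- round(0.3 * offspring_rate * pf)   # present at a typical date

  grazing_pct <- min(draw("grazing_time_pct"), 100)
  milk_per_pf <- draw("milk_fpcm_l_pf")
  fat <- draw("milk_fat_pct")
  prot <- draw("milk_protein_pct")
  # meat sales follow the herd: culled offspring at the 35-day slaughter
  # weight plus a 5% adult cull, rather than an independent per-ha draw
  # (independent draws make the meat/milk ratio physically inconsistent)
  species <- if (breed_group == "Florida") "goat" else "sheep"
  adult_w <- if (breed_group == "Florida") 55 else 70

  purch_forage <- draw("purchased_forage_kg_dm_pf") * pf
  purch_conc <- draw("purchased_concentrate_kg_dm_pf") * pf
  soy <- 0.12 * purch_conc                   # soybean share of concentrate
  fert_n <- draw("fert_n_kg_ha") * total_ha
  fert_p <- draw("fert_p_kg_ha") * total_ha
  fert_k <- draw("fert_k_kg_ha") * total_ha

  land <- rbind(
    land_parcel("barley_grain", grain, 2.7, "grain"),
    land_parcel("oats_forage", forage / 2, 4.8, "hay"),
    land_parcel("triticale_forage", forage / 2, 4.8, "silage_bag"),
    land_parcel("maize_silage", maize, 15.7, "silage_bag"),
    land_parcel("alfalfa", legumes, 14.7, "hay"),
    land_parcel("fallow", fallow, 0, "grazing"))
  land <- land[land$area_ha > 0, ]
  if (nrow(land)) {
    land$fert_n <- fert_n / max(sum(land$area_ha), 1)
    land$fert_p <- fert_p / max(sum(land$area_ha), 1)
    land$fert_k <- fert_k / max(sum(land$area_ha), 1)
  }

  herd <- herd_inventory(
    lactating_high = lact_split[1], lactating_medium = lact_split[2],
    lactating_low = lact_split[3], non_lactating = adults_dry,
    replacement_0_4 = round(repl * 0.3), replacement_4_12 = round(repl * 0.7),
    studs = max(1, round(pf / 40)), offspring = offspring,
    live_weight_kg = c(adult = if (breed_group == "Florida") 55 else 70),
    genetic_value = genetic_value)

  purchases <- purchase_ledger(
    forage_kg = purch_forage, concentrate_kg = purch_conc, soybean_kg = soy,
    fertilizer_n_kg = fert_n, fertilizer_p2o5_kg = fert_p * 2.292,
    fertilizer_k2o_kg = fert_k * 1.205,
    plastic_kg = 0.68 * (maize * 15.7 + forage / 2 * 4.8),
    pesticide_treated_ha = grain + forage)

  milk_total <- milk_per_pf * pf
  suckled <- 35 * offspring
  culled <- max(0, 91.4 + 0.97 * pf)
  lw_sold <- culled * gompertz_weight(35, species) + 0.05 * pf * adult_w
  farm_config(
    breed_group = breed_group, land = land, communal_pasture_ha = communal,
    herd = herd, purchases = purchases,
    grazing_time_fraction = grazing_pct / 100,
    milking_time_min = draw("milking_time_min"),
    milk_sold_L = max(milk_total - suckled, 0),
    milk_fat_pct = fat, milk_protein_pct = prot,
    live_weight_sold_kg = lw_sold,
    climate = gen_climate(seed = seed + 1L))
}

#' Generate synthetic metabolic-trial records
#'
#' Emulates the metabolic-chamber dataset behind the excreta regressions:
#' predictors are drawn from the dataset's truncated-normal moments (N intake
#' 20.9 +/- 8.5 g/d, OMD 0.633 +/- 0.10, DM intake 791.5 +/- 186 g/d, gross
#' protein 143.8 +/- 60.6, NDF 386.7 +/- 104.9) and each response is its
#' regression prediction plus Gaussian noise at the printed residual standard
#' error (urine 529 mL, feces 59.3 g, fecal N 1.26 g, urinary N 4.06 g).
#'
#' @param n Records to generate (>= 2).
#' @param seed Integer RNG seed.
#' @param noise_scale Multiplier on the residual SEs (0 gives exact model
#'   responses).
#' @param models Model list from [ff_models()].
#' @return Data frame with `omd`, `dmi_g`, `gp_g`, `ndf_g`, `n_intake_g`,
#'   `feces_g`, `urine_ml`, `n_feces_g`, `n_urine_g`.
#' @export
gen_metabolic_trials <- function(n, seed, noise_scale = 1,
                                 models = ff_models()) {
  stopifnot(n >= 2)
  set.seed(seed)
  omd <- pmin(rtruncnorm(n, 0.633, 0.10, lower = 0.2), 0.95)
  dmi <- rtruncnorm(n, 791.5, 186)
  gp <- rtruncnorm(n, 143.8, 60.6)
  ndf <- rtruncnorm(n, 386.7, 104.9)
  nin <- rtruncnorm(n, 20.9, 8.5)
  noise <- function(key) {
    noise_scale * stats::rnorm(n, 0, models[[key]]$residual_se)
  }
  feces <- vapply(seq_len(n), function(i) {
    eval_linear(models$feces, list(omd_pct = 100 * omd[i], dmi_g = dmi[i],
                                   gp_g = gp[i], ndf_g = ndf[i]))
  }, numeric(1)) + noise("feces")
  data.frame(
    omd = omd, dmi_g = dmi, gp_g = gp, ndf_g = ndf, n_intake_g = nin,
    feces_g = feces,
    urine_ml = models$urine$intercept +
      models$urine$coefficients[["n_intake_g"]] * nin + noise("urine"),
    n_feces_g = models$n_feces$intercept +
      models$n_feces$coefficients[["n_intake_g"]] * nin + noise("n_feces"),
    n_urine_g = models$n_urine$intercept +
      models$n_urine$coefficients[["n_intake_g"]] * nin + noise("n_urine"))
}

#' Generate synthetic forage-trial records
#'
#' Triticale: height 82.4 +/- 18.22 cm, days to ear emergence 154.2 +/- 36.5,
#' basal N 23.8 +/- 14.1 kg/ha, residual SE 669 kg DM/ha.  Oats: height
#' 70.5 +/- 28.0 cm (truncated > 0), residual SE 1211.
#'
#' @param n Records (>= 2).
#' @param seed Integer RNG seed.
#' @param crop `"triticale"` or `"oats"`.
#' @param noise_scale Multiplier on the residual SE.
#' @param models Model list from [ff_models()].
#' @return Data frame with `height_cm`, (`days_to_ear`, `n_basal_kg_ha` for
#'   triticale) and `yield_kg_dm_ha`.
#' @export
gen_forage_trials <- function(n, seed, crop = c("triticale", "oats"),
                              noise_scale = 1, models = ff_models()) {
  stopifnot(n >= 2)
  crop <- match.arg(crop)
  set.seed(seed)
  if (crop == "triticale") {
    h <- rtruncnorm(n, 82.4, 18.22, lower = 1)
    d <- rtruncnorm(n, 154.2, 36.5, lower = 1)
    nb <- rtruncnorm(n, 23.8, 14.1)
    spec <- models$triticale_yield
    y <- spec$intercept + spec$coefficients[["height_cm"]] * h +
      spec$coefficients[["days_to_ear"]] * d +
      spec$coefficients[["n_basal_kg_ha"]] * nb +
      noise_scale * stats::rnorm(n, 0, spec$residual_se)
    data.frame(height_cm = h, days_to_ear = d, n_basal_kg_ha = nb,
               yield_kg_dm_ha = y)
  } else {
    h <- rtruncnorm(n, 70.5, 28.0, lower = 1)
    spec <- models$oats_yield
    y <- spec$intercept + spec$coefficients[["height_cm"]] * h +
      noise_scale * stats::rnorm(n, 0, spec$residual_se)
    data.frame(height_cm = h, yield_kg_dm_ha = y)
  }
}

#' Generate a monthly climate series
#'
#' Continental-Mediterranean seasonal template: sinusoidal temperature with
#' summer maximum, winter-peaked rainfall, summer-peaked crop
#' evapotranspiration, plus seeded noise.  `t_max >= t_min` is guaranteed.
#'
#' @param seed Integer RNG seed.
#' @param months Months to generate (default 12, starting in January).
#' @param delta_t Uniform temperature offset (deg C) added to every month.
#' @return Data frame of [climate_month()] records.
#' @export
gen_climate <- function(seed, months = 12, delta_t = 0) {
  stopifnot(months >= 1)
  set.seed(seed)
  mo <- seq_len(months)
  phase <- 2 * pi * (mo - 7) / 12            # peak in July
  t_mean <- 14 + 9.5 * cos(phase) + stats::rnorm(months, 0, 0.8)
  spread <- 6 + 2 * cos(phase) + abs(stats::rnorm(months, 0, 0.5))
  rain <- pmax(0, 35 - 22 * cos(phase) + stats::rnorm(months, 0, 8))
  etc <- pmax(0, 55 + 50 * cos(phase) + stats::rnorm(months, 0, 6))
  climate_month(month = ((mo - 1) %% 12) + 1,
                t_max = t_mean + spread / 2 + delta_t,
                t_min = t_mean - spread / 2 + delta_t,
                rainfall_mm = rain,
                relative_humidity_pct = pmin(95, pmax(25,
                  60 - 15 * cos(phase) + stats::rnorm(months, 0, 5))),
                etc_mm = etc)
}
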