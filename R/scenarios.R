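#' Mitigation scenario specification
#'
#' A named, parameterized transformation of a baseline farm.  Groups follow
#' the surveyed practice families: genetic improvement (sheep of the
#' autochthonous breed only), animal inventory, purchased feed, forage
#' management, electrical supply, and climate change.
#'
#' @param name Scenario label.
#' @param group One of `"genetic_improvement"`, `"animal_inventory"`,
#'   `"purchased_feed"`, `"forage_management"`, `"electrical_supply"`,
#'   `"climate_change"`.
#' @param parameters Named list of parameters, e.g. `gv_increase_pct`,
#'   `replacement_cut_pct`, `unproductive_cut_pct`, `offspring_deaths_cut_pct`,
#'   `milking_time_cut_pct`, `delta_t_c`, `substitution`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, group, parameters = list()) {
  group <- match.arg(group, c("genetic_improvement", "animal_inventory",
                              "purchased_feed", "forage_management",
                              "electrical_supply", "climate_change"))
  pct <- grepl("_pct$", names(parameters))
  for (p in names(parameters)[pct]) {
    assert_fraction(parameters[[p]], p, 0, 100)
  }
  if (!is.null(parameters$delta_t_c)) {
    assert_nonneg(parameters$delta_t_c, "delta_t_c")
  }
  structure(list(name = name, group = group, parameters = parameters),
            class = "scenario_spec")
}

#' The surveyed scenario battery
#'
#' Builds the standard list of mitigation scenarios applicable to a breed
#' group: genetic value +5/10/15% (autochthonous sheep only), herd-inventory
#' cuts, feed substitutions, forage-management changes (grazing scenarios not
#' in goats), a 10% milking-energy cut, and a +2 degC temperature rise.
#'
#' @param breed_group Breed group of the baseline farm.
#' @return List of [scenario_spec()] objects.
#' @export
standard_scenarios <- function(breed_group = c("Manchega", "Foreigners",
                                               "Florida")) {
  breed_group <- match.arg(breed_group)
  sc <- list()
  if (breed_group == "Manchega") {
    for (g in c(5, 10, 15)) {
      sc[[paste0("genetic_value_+", g, "%")]] <-
        scenario_spec(paste0("genetic_value_+", g, "%"),
                      "genetic_improvement", list(gv_increase_pct = g))
    }
  }
  sc[["<10%_unproductive_females"]] <- scenario_spec(
    "<10%_unproductive_females", "animal_inventory",
    list(unproductive_cut_pct = 10))
  sc[["<5%_replacement"]] <- scenario_spec(
    "<5%_replacement", "animal_inventory", list(replacement_cut_pct = 5))
  sc[["soybean_to_peas"]] <- scenario_spec(
    "soybean_to_peas", "purchased_feed", list(substitution = "soybean_peas"))
  sc[["fibrous_concentrate"]] <- scenario_spec(
    "fibrous_concentrate", "purchased_feed",
    list(substitution = "fibrous_concentrate"))
  sc[["milk_replacer"]] <- scenario_spec(
    "milk_replacer", "purchased_feed", list(substitution = "milk_replacer"))
  sc[["silage_bags"]] <- scenario_spec(
    "silage_bags", "forage_management", list(silage_method = "silage_bag"))
  sc[["silage_round_bales"]] <- scenario_spec(
    "silage_round_bales", "forage_management",
    list(silage_method = "silage_round_bale"))
  if (breed_group != "Florida") {
    sc[["triticale_grazing_100d"]] <- scenario_spec(
      "triticale_grazing_100d", "forage_management",
      list(grazing_days = 100))
  }
  sc[["high_rfv_oat_hay"]] <- scenario_spec(
    "high_rfv_oat_hay", "forage_management", list(oat_hay_rfv = "high"))
  sc[["-10%_milking_energy"]] <- scenario_spec(
    "-10%_milking_energy", "electrical_supply",
    list(milking_time_cut_pct = 10))
  if (breed_group == "Manchega") {
    sc[["temperature_+2C"]] <- scenario_spec(
      "temperature_+2C", "climate_change", list(delta_t_c = 2))
  }
  sc
}

#' Apply a scenario to a baseline farm
#'
#' Pure transformation: returns a new farm configuration, never mutating the
#' baseline; the changes made are recorded in a `diff` attribute.  Breed
#' restrictions are enforced (genetic improvement only for the autochthonous
#' sheep breed; grazing scenarios not for goats).
#'
#' @param baseline A [farm_config()].
#' @param s A [scenario_spec()].
#' @param factors Factor list from [ff_factors()].
#' @param response Temperature-response table (see
#'   [ff_temperature_response()]).
#' @return A new `farm_config` with a `diff` attribute (named list of changed
#'   fields) and possibly a `diet` attribute consumed by [simulate_farm()].
#' @export
apply_scenario <- function(baseline, s, factors = ff_factors(),
                           response = ff_temperature_response()) {
  stopifnot(inherits(baseline, "farm_config"), inherits(s, "scenario_spec"))
  farm <- baseline
  diff <- list()
  diet <- list()
  par <- s$parameters

  if (s$group == "genetic_improvement") {
    if (farm$breed_group != "Manchega") {
      stop("genetic-improvement scenarios apply to the Manchega breed only",
           call. = FALSE)
    }
    rem <- genetic_value_reduction(
      gv_initial = farm$herd$genetic_value,
      increase_pct = par$gv_increase_pct,
      milk_sold_L = farm$milk_sold_L,
      milk_suckled_L = factors$milk_suckled_l_per_offspring *
        farm$herd$counts[["offspring"]],
      n_adults = present_females(farm$herd))
    farm$herd <- scale_adults(farm$herd, -rem)
    farm$herd$genetic_value <- farm$herd$genetic_value *
      (1 + par$gv_increase_pct / 100)
    diff$adults_removed <- rem
  } else if (s$group == "animal_inventory") {
    if (!is.null(par$unproductive_cut_pct)) {
      cut <- round(farm$herd$counts[["non_lactating"]] *
                     par$unproductive_cut_pct / 100)
      farm$herd$counts[["non_lactating"]] <-
        farm$herd$counts[["non_lactating"]] - cut
      diff$non_lactating_removed <- cut
    }
    if (!is.null(par$replacement_cut_pct)) {
      for (cl in c("replacement_0_4", "replacement_4_12")) {
        cut <- round(farm$herd$counts[[cl]] * par$replacement_cut_pct / 100)
        farm$herd$counts[[cl]] <- farm$herd$counts[[cl]] - cut
        diff[[paste0(cl, "_removed")]] <- cut
      }
    }
    if (!is.null(par$offspring_deaths_cut_pct)) {
      extra <- round(farm$herd$counts[["offspring"]] *
                       par$offspring_deaths_cut_pct / 100)
      farm$herd$counts[["offspring"]] <-
        farm$herd$counts[["offspring"]] + extra
      farm$live_weight_sold_kg <- farm$live_weight_sold_kg +
        extra * gompertz_weight(35, if (farm$breed_group == "Florida")
          "goat" else "sheep")
      diff$offspring_saved <- extra
    }
  } else if (s$group == "purchased_feed") {
    if (identical(par$substitution, "soybean_peas")) {
      farm$purchases$peas_kg <- (farm$purchases$peas_kg %||% 0) +
        farm$purchases$soybean_kg
      diff$soybean_moved_to_peas <- farm$purchases$soybean_kg
      farm$purchases$soybean_kg <- 0
    } else if (identical(par$substitution, "fibrous_concentrate")) {
      diet$concentrate <- "concentrate_byproduct"
      diff$concentrate <- "concentrate_byproduct"
    } else if (identical(par$substitution, "milk_replacer")) {
      suckled <- factors$milk_suckled_l_per_offspring *
        farm$herd$counts[["offspring"]]
      farm$milk_sold_L <- farm$milk_sold_L + suckled
      farm$purchases$milk_replacer_kg <- farm$purchases$milk_replacer_kg +
        0.2 * suckled                        # 200 g powder per liter fed
      diff$suckled_milk_marketed_L <- suckled
    }
  } else if (s$group == "forage_management") {
    if (!is.null(par$silage_method)) {
      idx <- grepl("silage", farm$land$use)
      farm$land$use[idx] <- par$silage_method
      diff$silage_method <- par$silage_method
    }
    if (!is.null(par$grazing_days)) {
      if (farm$breed_group == "Florida") {
        stop("triticale grazing scenarios do not apply to goats",
             call. = FALSE)
      }
      add <- par$grazing_days / 365
      farm$grazing_time_fraction <- min(1, farm$grazing_time_fraction + add)
      idx <- farm$land$crop == "triticale_forage"
      farm$land$use[idx] <- "grazing"
      # grazed spring triticale substitutes purchased forage, it does not
      # add to the diet on top of it
      extra_graze <- add * present_females(farm$herd) * 1.5 * 365
      cut_forage <- min(farm$purchases$forage_kg, extra_graze)
      farm$purchases$forage_kg <- farm$purchases$forage_kg - cut_forage
      diff$grazing_time_fraction <- farm$grazing_time_fraction
      diff$purchased_forage_replaced_kg <- cut_forage
      if (!is.null(par$concentrate_cut_pct)) {
        cut <- farm$purchases$concentrate_kg * par$concentrate_cut_pct / 100
        farm$purchases$concentrate_kg <-
          farm$purchases$concentrate_kg - cut
        diff$concentrate_cut_kg <- cut
      }
    }
    if (!is.null(par$oat_hay_rfv)) {
      diet$purchased_forage <- "oat_hay_high_rfv"
      diff$purchased_forage <- "oat_hay_high_rfv"
    }
  } else if (s$group == "electrical_supply") {
    farm$milking_time_min <- farm$milking_time_min *
      (1 - par$milking_time_cut_pct / 100)
    diff$milking_time_min <- farm$milking_time_min
  } else if (s$group == "climate_change") {
    farm <- temperature_scenario(farm, par$delta_t_c, response)
    diff$delta_t_c <- par$delta_t_c
  }

  validate_farm(farm)
  attr(farm, "diff") <- diff
  attr(farm, "diet") <- diet
  farm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scale_adults <- function(herd, delta) {
  cls <- c("lactating_high", "lactating_medium", "lactating_low",
           "non_lactating")
  tot <- sum(herd$counts[cls])
  if (tot <= 0) return(herd)
  herd$counts[cls] <- pmax(0, herd$counts[cls] * (1 + delta / tot))
  herd
}

#' Adults removable through genetic improvement
#'
#' Raising the flock genetic value raises milk per lactation by 5.3 L per
#' index point; the extra milk per ewe, summed over the flock and divided by
#' the per-ewe total milk (marketed plus suckled), is the number of adults
#' that can be removed without changing total milk output (floored).
#'
#' @param gv_initial Current flock genetic value (> 0).
#' @param increase_pct Genetic value increase (%).
#' @param milk_sold_L,milk_suckled_L Annual marketed and offspring-suckled
#'   milk (L).
#' @param n_adults Present females.
#' @param models Model list from [ff_models()].
#' @return Whole number of removable adults.
#' @export
genetic_value_reduction <- function(gv_initial, increase_pct, milk_sold_L,
                                    milk_suckled_L, n_adults,
                                    models = ff_models()) {
  if (increase_pct == 0) return(0)
  gv_final <- gv_initial * (1 + increase_pct / 100)
  slope <- models$milk_gv$coefficients[["gv"]]
  extra_per_ewe <- slope * (gv_final - gv_initial)
  per_ewe_milk <- (milk_sold_L + milk_suckled_L) / n_adults
  if (per_ewe_milk <= 0) return(0)
  floor(n_adults * extra_per_ewe / per_ewe_milk)
}

#' Milk-yield response to a temperature rise
#'
#' Applies per-season milk, fat and protein depression coefficients
#' (% per deg C) to the breeding-season months and shifts the climate series
#' by `delta_t`.  The shipped default table yields a 0.46% annual milk loss
#' at +2 deg C; the response equations themselves are farm-scheme specific
#' and fully replaceable.
#'
#' @param baseline A [farm_config()].
#' @param delta_t Temperature increase (deg C), >= 0.
#' @param response Table from [ff_temperature_response()].
#' @return A transformed `farm_config`.
#' @export
temperature_scenario <- function(baseline, delta_t,
                                 response = ff_temperature_response()) {
  assert_nonneg(delta_t, "delta_t")
  if (!nrow(response)) stop("temperature response table is empty",
                            call. = FALSE)
  farm <- baseline
  if (delta_t == 0) return(farm)
  # breeding seasons contribute equally to annual production
  milk_loss <- delta_t * mean(response$milk_loss_pct_per_c) / 100
  fat_loss <- delta_t * mean(response$fat_loss_pct_per_c) / 100
  prot_loss <- delta_t * mean(response$protein_loss_pct_per_c) / 100
  farm$milk_sold_L <- farm$milk_sold_L * (1 - milk_loss)
  farm$milk_fat_pct <- farm$milk_fat_pct * (1 - fat_loss)
  farm$milk_protein_pct <- farm$milk_protein_pct * (1 - prot_loss)
  farm$climate$t_max <- farm$climate$t_max + delta_t
  farm$climate$t_min <- farm$climate$t_min + delta_t
  farm
}

#' Run a scenario battery against a baseline
#'
#' Simulates the baseline and every scenario, reporting total CO2e per
#' hectare, per livestock unit and per liter of FPCM with percent changes
#' against the baseline.  A failing scenario is recorded in its row
#' (`error` column) and the run continues.
#'
#' @param baseline A [farm_config()].
#' @param scenarios List of [scenario_spec()] (default
#'   [standard_scenarios()] for the farm's breed).
#' @param ... Passed to [simulate_farm()].
#' @return Data frame: one baseline row (0% change) plus one row per
#'   scenario with `co2e_ha`, `co2e_lu`, `co2e_l_fpcm` and `change_*_pct`.
#' @export
run_scenarios <- function(baseline, scenarios = NULL, ...) {
  if (is.null(scenarios)) scenarios <- standard_scenarios(baseline$breed_group)
  base_rep <- simulate_farm(baseline, ...)
  row_of <- function(name, rep, err = NA_character_) {
    fu <- if (is.null(rep)) c(ha = NA, LU = NA, L_FPCM = NA) else
      rep$footprint$per_fu
    data.frame(scenario = name,
               co2e_ha = unname(fu[["ha"]]), co2e_lu = unname(fu[["LU"]]),
               co2e_l_fpcm = unname(fu[["L_FPCM"]]), error = err,
               stringsAsFactors = FALSE)
  }
  out <- row_of("baseline", base_rep)
  for (s in scenarios) {
    rep <- tryCatch({
      farm2 <- apply_scenario(baseline, s)
      simulate_farm(farm2, diet = attr(farm2, "diet"), ...)
    }, error = function(e) e)
    if (inherits(rep, "error")) {
      out <- rbind(out, row_of(s$name, NULL, conditionMessage(rep)))
    } else {
      out <- rbind(out, row_of(s$name, rep))
    }
  }
  for (col in c("co2e_ha", "co2e_lu", "co2e_l_fpcm")) {
    out[[paste0("change_", col, "_pct")]] <-
      100 * (out[[col]] - out[[col]][1]) / out[[col]][1]
  }
  out
}
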