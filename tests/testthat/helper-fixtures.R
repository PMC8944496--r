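# Small deterministic fixture farm used across tests: built in code, not
# drawn from the survey moments, so expected values stay hand-checkable.
fixture_farm <- function(breed = "Manchega") {
  land <- rbind(
    land_parcel("barley_grain", 10, 2.7, "grain"),
    land_parcel("triticale_forage", 8, 4.8, "silage_bag", fert_n = 40),
    land_parcel("oats_forage", 6, 4.8, "hay"),
    land_parcel("alfalfa", 4, 14, "hay"),
    land_parcel("fallow", 5, 0, "grazing"))
  herd <- herd_inventory(
    lactating_high = 90, lactating_medium = 60, lactating_low = 50,
    non_lactating = 60, replacement_0_4 = 20, replacement_4_12 = 50,
    studs = 6, offspring = 150, genetic_value = 9)
  farm_config(
    breed_group = breed, land = land, communal_pasture_ha = 60, herd = herd,
    purchases = purchase_ledger(forage_kg = 60000, concentrate_kg = 80000,
                                soybean_kg = 9000, fertilizer_n_kg = 1500,
                                fertilizer_p2o5_kg = 500,
                                fertilizer_k2o_kg = 300, plastic_kg = 150,
                                pesticide_treated_ha = 20),
    grazing_time_fraction = 0.25, milking_time_min = 120,
    milk_sold_L = 75000, milk_fat_pct = 7.0, milk_protein_pct = 5.7,
    live_weight_sold_kg = 4500, climate = gen_climate(seed = 7L))
}

# Independent dot-product oracle for linear model evaluation: plain loop,
# no shared code with eval_linear.
oracle_linear <- function(intercept, betas, xs) {
  acc <- intercept
  for (nm in names(betas)) acc <- acc + betas[[nm]] * xs[[nm]]
  acc
}
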