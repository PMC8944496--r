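baseline <- fixture_farm()

test_that("scenario application is pure and restrictions are enforced", {
  before <- baseline$herd$counts
  s <- scenario_spec("cut", "animal_inventory", list(replacement_cut_pct = 5))
  f2 <- apply_scenario(baseline, s)
  expect_equal(baseline$herd$counts, before)     # baseline untouched
  expect_lt(sum(f2$herd$counts), sum(before))
  goat <- fixture_farm("Florida")
  expect_error(
    apply_scenario(goat, scenario_spec("gv", "genetic_improvement",
                                       list(gv_increase_pct = 5))),
    "Manchega")
  expect_error(
    apply_scenario(goat, scenario_spec("gr", "forage_management",
                                       list(grazing_days = 100))),
    "goats")
})

test_that("a zero-magnitude scenario is the identity", {
  s <- scenario_spec("none", "climate_change", list(delta_t_c = 0))
  f2 <- apply_scenario(baseline, s)
  expect_equal(f2$milk_sold_L, baseline$milk_sold_L)
  expect_equal(f2$climate, baseline$climate)
})

test_that("genetic improvement removes adults while conserving milk", {
  expect_equal(genetic_value_reduction(7, 0, 1000, 100, 10), 0)
  # constructed 2-ewe flock: parameters chosen so the extra milk equals one
  # ewe's production exactly
  # extra milk 5.3 x 10 = 53 L/ewe; per-ewe milk 106 L -> exactly one ewe
  expect_equal(
    genetic_value_reduction(gv_initial = 10, increase_pct = 100,
                            milk_sold_L = 212, milk_suckled_L = 0,
                            n_adults = 2),
    1)
  s <- scenario_spec("gv10", "genetic_improvement", list(gv_increase_pct = 10))
  f2 <- apply_scenario(baseline, s)
  expect_lt(present_females(f2$herd), present_females(baseline$herd))
  expect_equal(f2$milk_sold_L, baseline$milk_sold_L)
})

test_that("calibrated flocks place GV-driven herd cuts in the observed band", {
  # flock at the default genetic value: removals for +5% to +15% GV fall
  # between 0.47% and 2.38% of the adults
  for (pct in c(5, 10, 15)) {
    s <- scenario_spec("gv", "genetic_improvement",
                       list(gv_increase_pct = pct))
    f2 <- apply_scenario(baseline, s)
    removed <- present_females(baseline$herd) - present_females(f2$herd)
    frac <- 100 * removed / present_females(baseline$herd)
    expect_gte(frac, 0.47)
    expect_lte(frac, 2.38)
  }
})

test_that("the default temperature response loses 0.46% milk at +2 degC", {
  f2 <- temperature_scenario(baseline, 2)
  loss <- 100 * (1 - f2$milk_sold_L / baseline$milk_sold_L)
  expect_equal(loss, 0.46, tolerance = 1e-8)
  # monotone in the temperature rise
  losses <- vapply(c(0, 1, 2, 3), function(dt) {
    1 - temperature_scenario(baseline, dt)$milk_sold_L / baseline$milk_sold_L
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  expect_equal(temperature_scenario(baseline, 0)$milk_sold_L,
               baseline$milk_sold_L)
})

test_that("independent purchase-side scenarios commute", {
  s1 <- scenario_spec("peas", "purchased_feed",
                      list(substitution = "soybean_peas"))
  s2 <- scenario_spec("mr", "purchased_feed",
                      list(substitution = "milk_replacer"))
  a <- apply_scenario(apply_scenario(baseline, s1), s2)
  b <- apply_scenario(apply_scenario(baseline, s2), s1)
  expect_equal(unclass(a$purchases), unclass(b$purchases))
  expect_equal(a$milk_sold_L, b$milk_sold_L)
})

test_that("scenario comparison reports exact marginal effects", {
  tab <- run_scenarios(baseline, list(
    scenario_spec("-10%_milking", "electrical_supply",
                  list(milking_time_cut_pct = 10))))
  expect_equal(tab$change_co2e_ha_pct[1], 0)      # baseline row
  expect_equal(tab$change_co2e_lu_pct[1], 0)
  # electricity is linear in milking time: the CO2e drop equals 10% of the
  # electricity line
  base_rep <- simulate_farm(baseline)
  elec <- embedded_co2(baseline$purchases, lu = base_rep$herd$lu,
                       lactating_females = 200,
                       milking_time_min = 120)$electricity
  drop <- (tab$co2e_ha[1] - tab$co2e_ha[2]) * farm_area_ha(baseline)
  expect_equal(drop, 0.1 * elec, tolerance = 1e-6)
})

test_that("adding a tonne of concentrate raises per-ha CO2e by its factor", {
  f2 <- fixture_farm()
  f2$purchases$concentrate_kg <- f2$purchases$concentrate_kg + 1000
  r1 <- simulate_farm(baseline)
  r2 <- simulate_farm(f2)
  extra <- (r2$footprint$per_fu[["ha"]] - r1$footprint$per_fu[["ha"]]) *
    farm_area_ha(baseline)
  # embedded CO2 (300 kg) plus the feed's N-related and land-use terms
  expect_gt(extra, 300)
  embedded_only <- 0.3 * 1000
  expect_lt(abs(extra - embedded_only) / extra, 0.8)
})

test_that("a failing scenario is reported in its row, not fatal", {
  bad <- scenario_spec("gv", "genetic_improvement", list(gv_increase_pct = 5))
  tab <- run_scenarios(fixture_farm("Florida"), list(bad))
  expect_equal(nrow(tab), 2)
  expect_match(tab$error[2], "Manchega")
  expect_false(is.na(tab$co2e_ha[1]))
})
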