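test_that("FPCM normalizes to ~1 at the reference composition", {
  expect_equal(fpcm(1000, 6.5, 5.8), 1005.5)
  expect_equal(fpcm(0, 6.5, 5.8), 0)
  expect_gt(fpcm(1000, 7.5, 5.8), fpcm(1000, 6.5, 5.8))
})

test_that("the milk allocation factor follows the meat/milk ratio", {
  a0 <- allocation_factor(0, 1000)
  expect_equal(a0$AF, 1)
  a <- allocation_factor(85.7, 1500)
  expect_equal(a$R, 85.7 / 1500)
  expect_equal(a$AF, 1 - 5.7717 * 85.7 / 1500, tolerance = 1e-12)
  expect_equal(round(a$AF, 3), 0.670)
  rs <- seq(0, 0.15, by = 0.01)
  afs <- vapply(rs, function(r) allocation_factor(r * 1000, 1000)$AF,
                numeric(1))
  expect_true(all(diff(afs) < 0))            # strictly decreasing pre-clamp
  expect_equal(allocation_factor(1000, 1000)$AF, 0)  # clamped
  expect_error(allocation_factor(10, 0), "zero milk")
})

test_that("carbon footprint assembles PCF, SY, iLUC and CS correctly", {
  led <- emission_ledger(
    c("enteric", "purchased_inputs", "soybean", "iLUC", "sequestration"),
    c("CH4", "CO2", "CO2", "CO2", "CO2"),
    c(100, 500, 2980, 14.3, -300))
  fp <- carbon_footprint(led, area_ha = 10, lu = 20, pf = 100,
                         fpcm_L = 10000, af = 0.8)
  expect_equal(fp$sy, 2980)                  # 1 t soybean
  expect_equal(fp$iluc, 14.3)                # 100 m2 at 143 g/m2
  expect_equal(fp$cs, 300)
  expect_equal(fp$pcf_kg_co2e, 28 * 100 + 500)   # ordinary pathways only
  # TCF identity: TCF - PCF - SY - iLUC + CS == 0
  expect_equal(fp$tcf_kg_co2e - fp$pcf_kg_co2e - fp$sy - fp$iluc + fp$cs, 0)
  expect_equal(fp$per_fu[["ha"]], fp$tcf_kg_co2e / 10)
  expect_equal(fp$per_fu[["L_FPCM"]], 0.8 * fp$tcf_kg_co2e / 10000)
  # full cancellation: CS equal to PCF + SY + iLUC zeroes the TCF
  led0 <- emission_ledger(c("enteric", "sequestration"), c("CH4", "CO2"),
                          c(10, -280))
  fp0 <- carbon_footprint(led0, 1, 1, 1, 1)
  expect_equal(fp0$tcf_kg_co2e, 0)
})

test_that("per-FU footprints are scale invariant", {
  led <- emission_ledger(c("enteric", "soil_direct"), c("CH4", "N2O"),
                         c(50, 2))
  led2 <- emission_ledger(c("enteric", "soil_direct"), c("CH4", "N2O"),
                          c(100, 4))
  fp1 <- carbon_footprint(led, 10, 20, 100, 5000)
  fp2 <- carbon_footprint(led2, 20, 40, 200, 10000)
  expect_equal(fp1$per_fu, fp2$per_fu)
})

test_that("acidification and eutrophication apply the equivalence factors", {
  expect_equal(impact_potentials(nh3_kg = 1)$ap_kg_so2e, 1.89)
  expect_equal(impact_potentials(nh3_kg = 1)$ep_kg_no3e, 3.64)
  expect_equal(impact_potentials(po4_kg = 1)$ep_kg_no3e, 10.45)
  expect_equal(impact_potentials(nox_kg = 1)$ap_kg_so2e, 0.7)
  expect_equal(impact_potentials(nox_kg = 1)$ep_kg_no3e, 1.35)
  z <- impact_potentials()
  expect_equal(z$ap_kg_so2e, 0)
  expect_equal(z$ep_kg_no3e, 0)
})

test_that("water, energy and N footprints aggregate their components", {
  f <- fixture_farm()
  w <- water_energy_n_footprints(f, imports = list(barley = 1000),
                                 milk_L = 1000, heads = 0, diesel_L = 100,
                                 electricity_kwh = 100,
                                 n_imported_kg = 500,
                                 reactive_n_kg = c(nh3 = 10, no3 = 5))
  expect_equal(w$wf$cleaning, 2.2)           # 2.2 L per liter of milk
  expect_equal(w$ef$direct, 38.6 * 100 + 3.6 * 100)
  expect_equal(w$ef$indirect, 3.5 * 1000)    # barley MJ factor
  expect_equal(w$nf_total_kg, 500)
  expect_equal(w$nf_reactive_kg, 15)
  expect_equal(w$wf$partial, w$wf$blue + w$wf$grey)
  w0 <- water_energy_n_footprints(f, milk_L = 0, heads = 0)
  expect_equal(w0$ef$indirect, 0)
  expect_error(
    water_energy_n_footprints(f, imports = list(unobtainium = 1)),
    "unobtainium")
})

test_that("land use converts purchased feed through reference yields", {
  lu <- land_use(list(barley = 290), on_farm_area_m2 = 0, fpcm_L = 1000)
  expect_equal(lu$off_farm_m2, 1000)
  expect_equal(lu$off_m2_per_l, 1)
  lu0 <- land_use(list(), on_farm_area_m2 = 5000, fpcm_L = 1000)
  expect_equal(lu0$off_m2_per_l, 0)
  expect_equal(lu0$total_m2_per_l, 5)
  expect_error(land_use(list(moonrock = 1), 0, 100), "moonrock")
  expect_error(land_use(list(), 0, 0), "fpcm")
})
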