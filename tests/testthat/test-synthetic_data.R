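test_that("farm generation is deterministic per seed", {
  f1 <- gen_farm(7, "Manchega")
  f2 <- gen_farm(7, "Manchega")
  expect_equal(f1$herd$counts, f2$herd$counts)
  expect_equal(f1$purchases$concentrate_kg, f2$purchases$concentrate_kg)
  expect_equal(f1$climate, f2$climate)
  f3 <- gen_farm(8, "Manchega")
  expect_false(identical(f1$herd$counts, f3$herd$counts))
})

test_that("generated herds and grazing match the survey moments", {
  n <- 300
  animals <- vapply(seq_len(n), function(s) {
    sum(gen_farm(s, "Manchega")$herd$counts[
      c("lactating_high", "lactating_medium", "lactating_low",
        "non_lactating", "replacement_0_4", "replacement_4_12")])
  }, numeric(1))
  expect_lt(abs(mean(animals) - 1466), 3 * 980 / sqrt(n))
  graz <- vapply(seq_len(n), function(s) {
    gen_farm(s + 5000, "Foreigners")$grazing_time_fraction * 100
  }, numeric(1))
  expect_lt(abs(mean(graz) - 3.7), 3 * 7.1 / sqrt(n))
})

test_that("generated farms are internally consistent", {
  for (s in c(1, 23, 77)) {
    for (b in c("Manchega", "Foreigners", "Florida")) {
      f <- gen_farm(s, b)
      expect_silent(validate_farm(f))
      expect_lte(sum(f$land$area_ha), farm_area_ha(f) + 1e-9)
    }
  }
})

test_that("metabolic trials follow the dataset moments and models", {
  d0 <- gen_metabolic_trials(50, seed = 3, noise_scale = 0)
  models <- ff_models()
  # zero noise puts responses exactly on the model lines
  expect_equal(d0$urine_ml,
               -654.1 + 71.3 * d0$n_intake_g, tolerance = 1e-10)
  expect_equal(d0$n_feces_g, 1.30 + 0.24 * d0$n_intake_g, tolerance = 1e-10)
  d <- gen_metabolic_trials(313, seed = 5)
  expect_lt(abs(mean(d$n_intake_g) - 20.9), 3 * 8.5 / sqrt(313))
  # OLS refit of urine on N intake recovers the printed slope
  fit <- lm(urine_ml ~ n_intake_g, data = d)
  se <- summary(fit)$coefficients["n_intake_g", "Std. Error"]
  expect_lt(abs(coef(fit)[["n_intake_g"]] - 71.3), 2 * se)
})

test_that("forage trials regenerate the printed yield models", {
  t0 <- gen_forage_trials(30, seed = 2, crop = "triticale", noise_scale = 0)
  expect_equal(t0$yield_kg_dm_ha,
               -11952 + 133.2 * t0$height_cm + 33.9 * t0$days_to_ear +
                 62.9 * t0$n_basal_kg_ha, tolerance = 1e-10)
  tt <- gen_forage_trials(59, seed = 4, crop = "triticale")
  fit <- lm(yield_kg_dm_ha ~ height_cm + days_to_ear + n_basal_kg_ha,
            data = tt)
  se <- summary(fit)$coefficients["height_cm", "Std. Error"]
  expect_lt(abs(coef(fit)[["height_cm"]] - 133.2), 2 * se)
  oo <- gen_forage_trials(100, seed = 6, crop = "oats")
  expect_true(all(oo$height_cm > 0))
})

test_that("climate series are seasonal, reproducible and shiftable", {
  c1 <- gen_climate(9)
  c2 <- gen_climate(9)
  expect_equal(c1, c2)
  expect_true(all(c1$t_max >= c1$t_min))
  expect_gt(sum(gdd(c1$t_max, c1$t_min)), 0)
  cs <- gen_climate(9, delta_t = 2)
  expect_equal(cs$t_max, c1$t_max + 2)
  expect_equal(cs$t_min, c1$t_min + 2)
  # July warmer than January in the template
  expect_gt(c1$t_max[7], c1$t_max[1])
})
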