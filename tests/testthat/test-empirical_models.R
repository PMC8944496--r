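models <- ff_models()

test_that("eval_linear reproduces hand evaluations of the printed models", {
  # all-zero inputs return the intercept
  expect_equal(eval_linear(models$urine, list(n_intake_g = 0)), -654.1)
  # fecal N at the dataset mean N intake, one decimal
  expect_equal(round(eval_linear(models$n_feces, list(n_intake_g = 20.9)), 1),
               6.3)
  # triticale yield at the dataset predictor means
  expect_equal(eval_linear(models$triticale_yield,
                           list(height_cm = 82.4, days_to_ear = 154.2,
                                n_basal_kg_ha = 23.8)),
               5748.08, tolerance = 1e-8)
  expect_error(eval_linear(models$feces, list(omd_pct = 60)), "dmi_g")
})

test_that("eval_linear agrees with an independent dot-product oracle", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    nm <- paste0("x", seq_len(k))
    betas <- setNames(rnorm(k, 0, 10), nm)
    ic <- rnorm(1, 0, 100)
    xs <- setNames(as.list(rnorm(k, 0, 5)), nm)
    spec <- linear_model_spec("rand", ic, betas)
    expect_equal(eval_linear(spec, xs), oracle_linear(ic, betas, xs))
  }
})

test_that("demography clamps negative raw counts and matches hand values", {
  d0 <- demography(0)
  expect_equal(d0$replacement_females, 0)
  expect_equal(attr(d0, "raw")[["replacement_females"]], -136.7)
  d <- demography(1267)
  expect_equal(d$born_offspring, 2307.87, tolerance = 1e-8)
  expect_equal(d$culled_offspring, 1320.39, tolerance = 1e-8)
  expect_equal(d$adult_losses, 122.6 + 0.40 * 1267, tolerance = 1e-8)
})

test_that("excreta predictions reproduce the metabolic-chamber models", {
  e <- excreta_predict(0.633, 791.5, 143.8, 386.7, 20.9)
  expect_equal(round(e$n_feces_g, 1), 6.3)
  expect_equal(e$n_urine_g, 15.326, tolerance = 1e-8)
  expect_equal(e$feces_g_dm, 337.0585, tolerance = 1e-6)
  expect_equal(e$urine_ml, 836.07, tolerance = 1e-6)
  expect_true(attr(e, "n_excess"))       # independent fits overshoot slightly
  # percent-scale OMD must be rejected
  expect_error(excreta_predict(63.3, 791.5, 143.8, 386.7, 20.9), "omd")
})

test_that("replacement-animal N excretion follows the metabolic-weight models", {
  expect_equal(excreta_replacement(0), list(n_feces_g = 0.16, n_urine_g = 0))
  e1 <- excreta_replacement(1)
  expect_equal(e1$n_feces_g, 0.46)
  expect_equal(e1$n_urine_g, 0.3039)
  e2 <- excreta_replacement(2)
  expect_equal(e2$n_feces_g, 0.76)
  expect_equal(e2$n_urine_g, 0.6139)
})

test_that("forage yield models evaluate and clamp correctly", {
  expect_equal(forage_yield("oats", 70.5), 5264)
  expect_equal(forage_yield("oats", 23.5), 0)          # root of the line
  expect_warning(y <- forage_yield("oats", 70.5, days_to_ear = 100),
                 "ignored")
  expect_equal(y, 5264)
  expect_equal(forage_yield("triticale", 82.4, 154.2, 23.8),
               5748.08, tolerance = 1e-8)
  expect_error(forage_yield("triticale", 82.4), "days_to_ear")
  expect_error(forage_yield("oats", 0), "height")
})

test_that("Gompertz growth matches closed-form values and is monotone", {
  expect_equal(gompertz_weight(0, "sheep"), 68.59 * exp(-2.47))
  expect_equal(gompertz_weight(0, "goat"), 53.3 * exp(-1.9))
  expect_equal(gompertz_weight(1e7, "sheep"), 68.59, tolerance = 1e-6)
  ages <- seq(0, 480, by = 5)
  w <- gompertz_weight(ages, "sheep")
  expect_true(all(diff(w) > 0))
  expect_true(all(w < 68.59))
  wg <- gompertz_weight(ages, "goat")
  expect_true(all(diff(wg) > 0) && all(wg < 53.3))
})

test_that("growing degree-days clamp at the 4-degree base", {
  expect_equal(gdd(20, 10), 11)
  expect_equal(gdd(4, 4), 0)
  expect_equal(gdd(2, 0), 0)
  expect_error(gdd(5, 10), "t_max")
})

test_that("milk from genetic value is the printed line", {
  expect_equal(milk_from_genetic_value(0), 198.3)
  expect_equal(milk_from_genetic_value(10), 251.3)
  expect_equal(milk_from_genetic_value(-10), 145.3)
})

test_that("stepwise fitting recovers a noiseless linear truth exactly", {
  d <- data.frame(x = seq(-5, 5, length.out = 50))
  d$y <- 2 * d$x + 1
  fit <- fit_stepwise(d, "y", "x")
  expect_equal(unname(fit$spec$intercept), 1, tolerance = 1e-10)
  expect_equal(unname(fit$spec$coefficients[["x"]]), 2, tolerance = 1e-10)
  expect_equal(fit$diagnostics$r2, 1)
})

test_that("stepwise refuses perfectly collinear duplicates", {
  set.seed(3)
  d <- data.frame(x = rnorm(60))
  d$z <- d$x                                # exact copy
  d$y <- 3 * d$x + rnorm(60, 0, 0.5)
  fit <- fit_stepwise(d, "y", c("x", "z"))
  expect_length(fit$spec$coefficients, 1)
  expect_true(all(fit$diagnostics$vif <= 10))
})

test_that("stepwise on synthetic urine trials recovers the printed slope", {
  d <- gen_metabolic_trials(313, seed = 99)
  fit <- fit_stepwise(d, "urine_ml", c("n_intake_g", "omd", "ndf_g"))
  est <- fit$spec$coefficients[["n_intake_g"]]
  se <- summary(fit$fit)$coefficients["n_intake_g", "Std. Error"]
  expect_lt(abs(est - 71.3), 2 * se)
})

test_that("stepwise returns intercept-only when nothing is significant", {
  set.seed(8)
  d <- data.frame(x = rnorm(40), y = rnorm(40))
  fit <- fit_stepwise(d, "y", "x")
  expect_length(fit$spec$coefficients, 0)
})

test_that("a large simulated flock book identifies the demography lines", {
  # generative sanity at large n: the refit converges on the printed
  # coefficients (small-n coverage behavior is exercised in the whole-model
  # acceptance battery)
  spec <- models$born_offspring
  set.seed(314)
  d <- data.frame(present_females = flockfoot:::rtruncnorm(4000, 1267, 873))
  d$y <- spec$intercept + spec$coefficients[["present_females"]] *
    d$present_females + rnorm(4000, 0, spec$residual_se)
  fit <- lm(y ~ present_females, data = d)
  expect_equal(coef(fit)[["present_females"]], 1.91, tolerance = 0.05)
  expect_equal(coef(fit)[["(Intercept)"]], -112.1, tolerance = 0.5)
})
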