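#' Linear sub-model specification
#'
#' Container for a fitted or printed multiple-regression sub-model: intercept,
#' slope per predictor, residual standard error and fit size.  All of the
#' empirical sub-models (herd demography, excreta, forage yield, milk from
#' genetic value) are evaluated through the same [eval_linear()] path.
#'
#' @param name Model identifier.
#' @param intercept Intercept (model units).
#' @param coefficients Named numeric vector of slopes.
#' @param residual_se Residual standard error (model units); `NA` if unknown.
#' @param n Number of records behind the fit; `NA` if unknown.
#' @param r2 Coefficient of determination.
#' @return An object of class `linear_model_spec`.
#' @export
linear_model_spec <- function(name, intercept, coefficients,
                              residual_se = NA_real_, n = NA_integer_,
                              r2 = NA_real_) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(coefficients) && is.null(names(coefficients))) {
    stop("coefficients must be named by predictor", call. = FALSE)
  }
  if (is.finite(residual_se) && residual_se < 0) {
    stop("residual_se must be >= 0", call. = FALSE)
  }
  if (is.finite(n) && length(coefficients) && n < length(coefficients) + 1L) {
    stop("n must be >= number of coefficients + 1", call. = FALSE)
  }
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, residual_se = residual_se,
                 n = n, r2 = r2),
            class = "linear_model_spec")
}

#' Load the shipped regression sub-models
#'
#' Reads the coefficient CSV (`model, term, beta, beta_se, residual_se, n, r2`)
#' into a named list of [linear_model_spec()] objects.  Where two conflicting
#' printed values exist for a coefficient, the complete model strings are taken
#' as authoritative; editing the CSV swaps any choice.
#'
#' @param path Optional replacement CSV.
#' @return Named list of `linear_model_spec`.
#' @export
ff_models <- function(path = NULL) {
  tab <- ff_read_csv(path, "model_coefficients.csv",
                     c("model", "term", "beta", "residual_se", "n", "r2"))
  specs <- lapply(split(tab, tab$model), function(m) {
    ic <- m$beta[m$term == "(Intercept)"]
    sl <- m[m$term != "(Intercept)", ]
    linear_model_spec(name = m$model[1],
                      intercept = if (length(ic)) ic else 0,
                      coefficients = stats::setNames(sl$beta, sl$term),
                      residual_se = m$residual_se[1],
                      n = m$n[1], r2 = m$r2[1])
  })
  specs
}

#' Evaluate a linear sub-model
#'
#' Computes `intercept + sum(beta * x)` on a named input list/vector.  Exact
#' arithmetic on the given coefficients; no clamping here (callers that model
#' counts or masses clamp their own predictions).
#'
#' @param spec A [linear_model_spec()].
#' @param inputs Named list or vector covering every coefficient of `spec`.
#' @return Numeric prediction in model units.
#' @examples
#' m <- linear_model_spec("demo", 1, c(x = 2))
#' eval_linear(m, list(x = 3))  # 7
#' @export
eval_linear <- function(spec, inputs) {
  stopifnot(inherits(spec, "linear_model_spec"))
  inputs <- unlist(inputs)
  need <- names(spec$coefficients)
  miss <- setdiff(need, names(inputs))
  if (length(miss)) {
    stop("model '", spec$name, "' missing predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unname(spec$intercept + sum(spec$coefficients * inputs[need]))
}

clamp0 <- function(x) pmax(x, 0)   # x first so names survive

#' Herd demography from the number of present females
#'
#' The five flock-book regressions predict annual counts of replacement
#' females (4-12 months), born offspring, culled offspring, adult losses
#' (deaths/discards of breeding animals), and offspring deaths/abortions, all
#' as linear functions of the present females (PF).  Raw predictions can be
#' negative at small PF and are clamped at zero; the raw values are kept for
#' diagnostics.
#'
#' @param pf Present (breeding) females.
#' @param models Model list from [ff_models()].
#' @return A list of class `demography_counts` with clamped counts and a
#'   `raw` attribute.
#' @export
demography <- function(pf, models = ff_models()) {
  assert_nonneg(pf, "present_females")
  keys <- c("replacement_females", "born_offspring", "culled_offspring",
            "adult_losses", "offspring_deaths")
  raw <- vapply(keys, function(k) {
    eval_linear(models[[k]], list(present_females = pf))
  }, numeric(1))
  out <- as.list(clamp0(raw))
  attr(out, "raw") <- raw
  class(out) <- "demography_counts"
  out
}

#' Excreta production of lactating and dry females
#'
#' Per head and day: feces (g DM) from diet digestibility and intake
#' composition, urine volume (mL) and fecal/urinary N (g) from N intake.
#' These are the metabolic-chamber regressions for adult sheep fed at
#' maintenance.  Negative raw values are clamped at zero, and predicted
#' fecal + urinary N is capped at the N intake so the animal-level N balance
#' cannot go negative.
#'
#' @param omd Organic matter digestibility of the diet as a fraction in (0, 1].
#' @param dmi_g Dry-matter intake (g/head/day).
#' @param gp_g Gross (crude) protein intake (g/head/day).
#' @param ndf_g NDF intake (g/head/day).
#' @param n_intake_g N intake (g/head/day).
#' @param models Model list from [ff_models()].
#' @return List with `feces_g_dm`, `urine_ml`, `n_feces_g`, `n_urine_g` and a
#'   `raw` attribute.
#' @examples
#' excreta_predict(0.633, 791.5, 143.8, 386.7, 20.9)$n_feces_g  # ~6.3
#' @export
excreta_predict <- function(omd, dmi_g, gp_g, ndf_g, n_intake_g,
                            models = ff_models()) {
  if (!is.finite(omd) || omd <= 0 || omd > 1) {
    stop("omd must be a fraction in (0, 1]; got ", omd,
         " (percent-scale input?)", call. = FALSE)
  }
  assert_nonneg(c(dmi_g, gp_g, ndf_g, n_intake_g), "intake terms")
  raw <- c(
    feces_g_dm = eval_linear(models$feces,
                             list(omd_pct = 100 * omd, dmi_g = dmi_g,
                                  gp_g = gp_g, ndf_g = ndf_g)),
    urine_ml = eval_linear(models$urine, list(n_intake_g = n_intake_g)),
    n_feces_g = eval_linear(models$n_feces, list(n_intake_g = n_intake_g)),
    n_urine_g = eval_linear(models$n_urine, list(n_intake_g = n_intake_g)))
  out <- as.list(clamp0(raw))
  # The two N regressions were fitted independently, so near the dataset mean
  # their sum can slightly exceed intake; the predictions are reported as-is
  # (they are the printed models) and the exceedance is flagged for callers.
  attr(out, "n_excess") <- (out$n_feces_g + out$n_urine_g) > n_intake_g
  attr(out, "raw") <- raw
  out
}

#' Excreta N of replacement animals
#'
#' Fecal and urinary N (g/head/day) from N intake scaled by metabolic weight
#' (g N per kg live weight^0.75).
#'
#' @param n_intake_per_met_wt N intake per kg metabolic weight (g/kg LW^0.75).
#' @param models Model list from [ff_models()].
#' @return List with `n_feces_g` and `n_urine_g` (clamped at zero).
#' @export
excreta_replacement <- function(n_intake_per_met_wt, models = ff_models()) {
  assert_nonneg(n_intake_per_met_wt, "n_intake_per_met_wt")
  list(n_feces_g = clamp0(eval_linear(models$n_feces_replacement,
         list(n_intake_per_met_wt = n_intake_per_met_wt))),
       n_urine_g = clamp0(eval_linear(models$n_urine_replacement,
         list(n_intake_per_met_wt = n_intake_per_met_wt))))
}

#' Winter-cereal forage yield
#'
#' Dry-matter yield (kg DM/ha) of triticale (from plant height, days to ear
#' emergence and basal N) or oats (from plant height alone).  Raw predictions
#' are clamped at zero.
#'
#' @param crop `"triticale"` or `"oats"`.
#' @param height_cm Plant height (cm), > 0.
#' @param days_to_ear Days from sowing to inflorescence emergence (triticale).
#' @param n_basal_kg_ha Basal-dressing N (kg/ha; triticale).
#' @param models Model list from [ff_models()].
#' @return Yield in kg DM/ha.
#' @examples
#' forage_yield("oats", height_cm = 70.5)  # 5264
#' @export
forage_yield <- function(crop = c("triticale", "oats"), height_cm,
                         days_to_ear = NULL, n_basal_kg_ha = NULL,
                         models = ff_models()) {
  crop <- match.arg(crop)
  if (!is.finite(height_cm) || height_cm <= 0) {
    stop("height_cm must be > 0", call. = FALSE)
  }
  if (crop == "triticale") {
    if (is.null(days_to_ear) || is.null(n_basal_kg_ha)) {
      stop("triticale yield needs days_to_ear and n_basal_kg_ha", call. = FALSE)
    }
    raw <- eval_linear(models$triticale_yield,
                       list(height_cm = height_cm, days_to_ear = days_to_ear,
                            n_basal_kg_ha = n_basal_kg_ha))
  } else {
    if (!is.null(days_to_ear) || !is.null(n_basal_kg_ha)) {
      warning("oats model uses height only; days/N ignored", call. = FALSE)
    }
    raw <- eval_linear(models$oats_yield, list(height_cm = height_cm))
  }
  clamp0(raw)
}

#' Gompertz growth of lambs and kids
#'
#' Live weight (kg) at a given age: `b1 * exp(-b2 * exp(-b3 * t))`.
#' The shipped parameters are the flock-book fits (sheep: asymptote 68.59 kg,
#' shape 2.47, rate 0.01/day; goats: 53.3 kg, 1.9, 0.0046/day).
#'
#' @param age_days Age (days), >= 0.
#' @param species `"sheep"` or `"goat"`, selecting the default parameters.
#' @param params Optional list `(beta1, beta2, beta3)` overriding the defaults.
#' @return Live weight (kg); strictly increasing in age, bounded by `beta1`.
#' @export
gompertz_weight <- function(age_days, species = c("sheep", "goat"),
                            params = NULL) {
  assert_nonneg(age_days, "age_days")
  if (is.null(params)) {
    species <- match.arg(species)
    params <- if (species == "sheep") {
      list(beta1 = 68.59, beta2 = 2.47, beta3 = 0.01)
    } else {
      list(beta1 = 53.3, beta2 = 1.9, beta3 = 0.0046)
    }
  }
  if (params$beta1 <= 0 || params$beta3 <= 0) {
    stop("Gompertz parameters beta1 and beta3 must be > 0", call. = FALSE)
  }
  params$beta1 * exp(-params$beta2 * exp(-params$beta3 * age_days))
}

#' Growing degree-days
#'
#' Heat units for one day (or one monthly mean day): the mean of the maximum
#' and minimum temperature above a base temperature of 4 deg C, clamped at 0.
#'
#' @param t_max,t_min Daily maximum / minimum temperature (deg C).
#' @param t_base Base temperature (deg C), default 4.
#' @return Degree-days (>= 0).
#' @export
gdd <- function(t_max, t_min, t_base = 4) {
  if (any(t_max < t_min)) stop("t_max must be >= t_min", call. = FALSE)
  pmax(0, (t_max + t_min) / 2 - t_base)
}

#' Milk per lactation from the flock genetic value
#'
#' Liters of milk per lactation as a linear function of the national breeding
#' scheme's genetic value index: `198.3 + 5.3 * GV`.
#'
#' @param gv Genetic value index.
#' @param models Model list from [ff_models()].
#' @return Liters per lactation.
#' @export
milk_from_genetic_value <- function(gv, models = ff_models()) {
  eval_linear(models$milk_gv, list(gv = gv))
}
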