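#' Forward stepwise regression with collinearity screening
#'
#' Reproduces the model-building procedure behind the empirical sub-models:
#' forward ("step by step") selection at a 5% significance level, accepting at
#' each step the candidate that gives the highest R-squared, refusing any
#' predictor whose variance inflation factor in the grown model exceeds 10,
#' and reporting the Durbin-Watson statistic of the final residuals.  Ties in
#' R-squared are broken in favor of fewer predictors, then lexical predictor
#' order, so the procedure is deterministic.
#'
#' @param data A data frame with the response and candidate predictors.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha Entry significance level (default 0.05).
#' @param vif_max Maximum admissible VIF (default 10).
#' @return A list with `spec` (a [linear_model_spec()]), `fit` (the `lm`),
#'   `diagnostics` (`vif`, `durbin_watson`, `r2`) and `std_coefficients`
#'   (slopes on standardized predictors and response).
#' @export
fit_stepwise <- function(data, response, candidates, alpha = 0.05,
                         vif_max = 10) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 10) stop("need at least 10 records", call. = FALSE)
  if (!length(candidates)) stop("no candidate predictors", call. = FALSE)
  miss <- setdiff(c(response, candidates), names(data))
  if (length(miss)) {
    stop("column(s) not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  }

  selected <- character()
  repeat {
    pool <- sort(setdiff(candidates, selected))
    if (!length(pool)) break
    best <- NULL
    for (cand in pool) {
      terms <- c(selected, cand)
      fml <- stats::reformulate(terms, response)
      fit <- stats::lm(fml, data = data)
      if (anyNA(stats::coef(fit))) next        # rank-deficient: skip
      p <- summary(fit)$coefficients[cand, "Pr(>|t|)"]
      if (!is.finite(p) || p > alpha) next
      if (length(terms) > 1) {
        v <- vif(data[terms])
        if (any(!is.finite(v)) || any(v > vif_max)) next
      }
      r2 <- summary(fit)$r.squared
      if (is.null(best) || r2 > best$r2 + 1e-12) {
        best <- list(cand = cand, r2 = r2, fit = fit)
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best$cand)
  }

  fml <- if (length(selected)) stats::reformulate(selected, response) else
    stats::as.formula(paste(response, "~ 1"))
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  slopes <- cf[setdiff(names(cf), "(Intercept)")]
  std <- if (length(selected)) {
    sds <- vapply(data[selected], stats::sd, numeric(1))
    slopes * sds / stats::sd(data[[response]])
  } else numeric()
  spec <- linear_model_spec(
    name = response, intercept = unname(cf["(Intercept)"]),
    coefficients = slopes, residual_se = sm$sigma,
    n = nrow(data), r2 = sm$r.squared)
  diag <- list(
    vif = if (length(selected) > 1) vif(data[selected]) else
      stats::setNames(rep(1, length(selected)), selected),
    durbin_watson = durbin_watson(stats::residuals(fit)),
    r2 = sm$r.squared)
  list(spec = spec, fit = fit, diagnostics = diag, std_coefficients = std)
}

#' Variance inflation factors and the Durbin-Watson statistic
#'
#' `vif()` computes, for every column of the design, `1 / (1 - R2_j)` where
#' `R2_j` is from regressing that column on the others; perfect collinearity
#' yields `Inf` (flagged, not an error).  `durbin_watson()` is
#' `sum(diff(e)^2) / sum(e^2)` on an ordered residual vector; white-noise
#' residuals give values near 2.
#'
#' @param design Data frame or matrix of predictors (>= 1 column).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  if (!ncol(design)) stop("empty design", call. = FALSE)
  if (ncol(design) == 1L) {
    return(stats::setNames(1, names(design)))
  }
  vapply(names(design), function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(names(design), j), j),
                     data = design)
    # perfect collinearity is an expected outcome here, not a fit problem
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' @rdname vif
#' @param residuals Ordered residual vector (length >= 2).
#' @return `durbin_watson()`: scalar in [0, 4].
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need >= 2 residuals", call. = FALSE)
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Collinearity and autocorrelation screen
#'
#' Convenience wrapper bundling [vif()] on a design with [durbin_watson()] on
#' the residuals of a fitted model, as used when screening candidate models.
#'
#' @param design Predictor data frame/matrix.
#' @param residuals Residual vector.
#' @return List with `vif` and `durbin_watson`.
#' @export
collinearity <- function(design, residuals) {
  list(vif = vif(design), durbin_watson = durbin_watson(residuals))
}
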