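#' Default coefficient and emission-factor tables
#'
#' All numeric constants used by the simulator live in plain-text CSV tables
#' under `inst/extdata` so that every factor is auditable and user-overridable.
#' `ff_factors()` returns the scalar emission/conversion factors as a named
#' list; the other loaders return data frames.  Passing a `path` substitutes a
#' user table with the same column layout.
#'
#' @param path Optional path to a replacement CSV with identical columns.
#' @return `ff_factors()`: a named list of scalars. Table loaders: data frames.
#' @export
ff_factors <- function(path = NULL) {
  tab <- ff_read_csv(path, "emission_factors.csv", c("factor", "value"))
  out <- as.list(as.numeric(tab$value))
  names(out) <- tab$factor
  out
}

#' @rdname ff_factors
#' @export
ff_lu_table <- function(path = NULL) {
  ff_read_csv(path, "lu_coefficients.csv", c("class", "coefficient"))
}

#' @rdname ff_factors
#' @export
ff_feed_table <- function(path = NULL) {
  ff_read_csv(path, "feed_composition.csv", c("name", "dm", "cp", "ndf", "omd"))
}

#' @rdname ff_factors
#' @export
ff_yield_table <- function(path = NULL) {
  ff_read_csv(path, "offfarm_yields.csv", c("product", "yield_t_ha"))
}

#' @rdname ff_factors
#' @export
ff_water_energy_table <- function(path = NULL) {
  ff_read_csv(path, "water_energy_factors.csv",
              c("product", "water_green_m3_t", "water_blue_m3_t",
                "water_grey_m3_t", "energy_mj_kg"))
}

#' @rdname ff_factors
#' @export
ff_fixation_table <- function(path = NULL) {
  ff_read_csv(path, "legume_fixation.csv", c("crop", "kg_n_ha"))
}

#' @rdname ff_factors
#' @export
ff_requirement_table <- function(path = NULL) {
  ff_read_csv(path, "requirement_coefficients.csv", c("class", "ne_maint_mcal_d"))
}

#' @rdname ff_factors
#' @export
ff_temperature_response <- function(path = NULL) {
  ff_read_csv(path, "temperature_response.csv",
              c("season", "milk_loss_pct_per_c"))
}

#' @rdname ff_factors
#' @export
ff_survey_moments <- function(path = NULL) {
  ff_read_csv(path, "survey_moments.csv", c("breed_group", "field", "mean", "sd"))
}

# Shared CSV reader: resolves the shipped default when path is NULL and
# validates the expected columns with an explicit error path.  Shipped
# defaults are immutable per session, so they are cached after first read.
.ff_cache <- new.env(parent = emptyenv())

ff_read_csv <- function(path, default_file, required_cols) {
  if (is.null(path)) {
    if (!is.null(.ff_cache[[default_file]])) {
      return(.ff_cache[[default_file]])
    }
    path <- system.file("extdata", default_file, package = "flockfoot")
    tab <- ff_read_csv(path, default_file, required_cols)
    .ff_cache[[default_file]] <- tab
    return(tab)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("coefficient table not found: ", default_file, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop("table '", basename(path), "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

# Internal numeric guards used across modules ---------------------------------

assert_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be finite and >= 0", call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, what, lo = 0, hi = 1) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(what, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(x)
}
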