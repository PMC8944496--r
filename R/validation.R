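#' Model-validation battery
#'
#' The five indices used to judge every sub-model against observations:
#' coefficient of determination (r2), Willmott's index of agreement (d),
#' root mean square error (RMSE), mean bias error (MBE, computed as
#' `mean(simulated - observed)` so a positive value means overestimation),
#' and Nash-Sutcliffe model efficiency (EF; 1 is a perfect match, values at
#' or below 0 mean the observed mean predicts no worse than the model;
#' mathematically EF is unbounded below).
#'
#' @param observed,simulated Numeric vectors of equal length >= 2.
#' @return An object of class `validation_report`: list with `r2`, `d`,
#'   `rmse`, `mbe`, `ef`, `n`.
#' @examples
#' validate_model(c(1, 2, 3), c(2, 3, 4))  # mbe +1, rmse 1
#' @export
validate_model <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  if (stats::sd(observed) == 0) {
    stop("observed is constant: r2 and EF undefined", call. = FALSE)
  }
  err <- simulated - observed
  obar <- mean(observed)
  rmse <- sqrt(mean(err^2))
  mbe <- mean(err)
  ef <- 1 - sum(err^2) / sum((observed - obar)^2)
  d <- if (all(err == 0)) 1 else {
    1 - sum(err^2) /
      sum((abs(simulated - obar) + abs(observed - obar))^2)
  }
  r2 <- if (stats::sd(simulated) == 0) 0 else stats::cor(observed, simulated)^2
  structure(list(r2 = r2, d = d, rmse = rmse, mbe = mbe, ef = ef, n = n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation (n = %d): r2 %.3f | d %.3f | RMSE %.4g | MBE %+.4g | EF %.3f\n",
              x$n, x$r2, x$d, x$rmse, x$mbe, x$ef))
  invisible(x)
}

#' Write a validation report
#'
#' Serializes one or more [validate_model()] reports to CSV or JSON, one row
#' per model, mirroring the evaluation table layout (d, r2, RMSE, MBE, EF).
#'
#' @param reports Named list of `validation_report` objects.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_validation_reports <- function(reports, path) {
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, n = r$n, d = r$d, r2 = r$r2, rmse = r$rmse,
               mbe = r$mbe, ef = r$ef)
  }))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
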