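# Calibration-curve fitting and bioanalytical performance statistics:
# internal-standard correction, LOD/LOQ from the standard deviation of
# the Y-intercept, precision (RSD), accuracy, recovery, and
# inter-/intra-day aggregation of a validation campaign.

#' Internal-standard-corrected response
#'
#' @param analyte_area analyte peak area.
#' @param is_area internal-standard peak area (> 0).
#' @return Dimensionless response ratio, vectorized.
#' @export
is_ratio <- function(analyte_area, is_area) {
  if (any(is_area <= 0)) {
    stop("internal-standard area must be > 0 (degenerate sample)",
         call. = FALSE)
  }
  analyte_area / is_area
}

#' Fit a linear calibration curve
#'
#' Unweighted ordinary least squares of the internal-standard-corrected
#' response against the nominal concentration. By default replicate rows
#' at the same level are averaged before fitting (the "average curve");
#' set `average_replicates = FALSE` to fit all replicates pooled.
#'
#' The standard deviation of the Y-intercept is the regression standard
#' error of the intercept estimate, the quantity behind the
#' SD-of-intercept LOD approach.
#'
#' @param levels data.frame with columns `concentration` (mg/L),
#'   `analyte_area`, `is_area`; or columns `concentration` and
#'   `response` if the ratio is already formed.
#' @param average_replicates average replicate responses per level
#'   before fitting (default `TRUE`).
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `sd_intercept`, `sd_slope`, `residual_df`, `n_levels`,
#'   and the underlying `lm` fit.
#' @export
fit_calibration <- function(levels, average_replicates = TRUE) {
  stopifnot(is.data.frame(levels), "concentration" %in% names(levels))
  if (!"response" %in% names(levels)) {
    stopifnot(all(c("analyte_area", "is_area") %in% names(levels)))
    levels$response <- is_ratio(levels$analyte_area, levels$is_area)
  }
  if (any(levels$concentration <= 0)) {
    stop("calibration concentrations must be > 0", call. = FALSE)
  }
  concs <- sort(unique(levels$concentration))
  if (length(concs) < 3) {
    stop("need >= 3 distinct calibration levels", call. = FALSE)
  }
  dat <- if (average_replicates) {
    stats::aggregate(response ~ concentration, data = levels, FUN = mean)
  } else {
    levels[, c("concentration", "response")]
  }
  fit <- stats::lm(response ~ concentration, data = dat)
  # noiseless synthetic curves trip summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- NA_real_  # constant response: R^2 undefined
  structure(
    list(slope = unname(stats::coef(fit)["concentration"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = r2,
         sd_intercept = sm$coefficients["(Intercept)", "Std. Error"],
         sd_slope = sm$coefficients["concentration", "Std. Error"],
         residual_df = fit$df.residual,
         n_levels = length(concs),
         fit = fit),
    class = "calibration_curve"
  )
}

#' Limits of detection and quantification from a calibration curve
#'
#' LOD = 3.3 x SD(Y-intercept) / slope; LOQ = 3 x LOD (ICH-style
#' SD-of-the-response-and-slope approach).
#'
#' @param curve a [fit_calibration()] result.
#' @return Named numeric vector `c(lod = , loq = )`, mg/L.
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  lod <- 3.3 * curve$sd_intercept / curve$slope
  c(lod = lod, loq = 3 * lod)
}

#' Concentration (or mass) from a response via a calibration curve
#'
#' Inverts the calibration line: (response - intercept) / slope.
#'
#' @param curve a [fit_calibration()] result.
#' @param response observed response(s).
#' @return Estimated concentration in the curve's units, vectorized.
#' @export
quantify <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  (response - curve$intercept) / curve$slope
}

#' Relative standard deviation, percent
#'
#' 100 x sample standard deviation / mean (n - 1 denominator).
#'
#' @param x numeric measurements (length >= 2).
#' @return RSD in percent.
#' @export
rsd_percent <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m == 0) stop("zero mean: RSD undefined", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Accuracy as percent of nominal
#'
#' 100 x mean(measured) / nominal.
#'
#' @param measured measured concentrations.
#' @param nominal nominal (theoretical) concentration, > 0.
#' @return Accuracy in percent.
#' @export
accuracy_percent <- function(measured, nominal) {
  stopifnot(length(measured) >= 1)
  if (nominal <= 0) stop("nominal concentration must be > 0", call. = FALSE)
  100 * mean(measured) / nominal
}

#' Recovery against a liquid-injection reference curve
#'
#' Quantifies the mass desorbed from the fiber on a reference calibration
#' curve built from direct liquid injections, and expresses it as a
#' percentage of the theoretical mass. A response at or below the curve
#' intercept maps to a non-positive mass and is flagged below range.
#'
#' @param response observed instrument response for the fiber desorption.
#' @param liquid_injection_curve reference [fit_calibration()] result
#'   whose concentration axis is mass (ng).
#' @param theoretical_mass expected mass on the fiber, ng (> 0).
#' @return List with `percent`, `quantified_mass` and `below_range`.
#' @export
recovery_percent <- function(response, liquid_injection_curve,
                             theoretical_mass) {
  if (theoretical_mass <= 0) {
    stop("theoretical_mass must be > 0", call. = FALSE)
  }
  mass <- quantify(liquid_injection_curve, response)
  list(percent = 100 * mass / theoretical_mass,
       quantified_mass = mass,
       below_range = mass <= 0)
}

# Per-day performance from one day's calibration + control rows.
daily_performance <- function(day_rows, control_levels) {
  cal <- day_rows[day_rows$role == "calibrant", ]
  ctl <- day_rows[day_rows$role == "control", ]
  curve <- fit_calibration(data.frame(
    concentration = cal$level_mg_L,
    analyte_area = cal$analyte_area,
    is_area = cal$is_area
  ))
  lims <- lod_loq(curve)
  per_level <- lapply(control_levels, function(lv) {
    rows <- ctl[ctl$level_mg_L == lv, ]
    if (nrow(rows) == 0) {
      return(data.frame(level = lv, n = 0, rsd = NA_real_,
                        accuracy = NA_real_))
    }
    conc <- quantify(curve, is_ratio(rows$analyte_area, rows$is_area))
    data.frame(level = lv, n = nrow(rows),
               rsd = if (nrow(rows) >= 2) rsd_percent(conc) else NA_real_,
               accuracy = accuracy_percent(conc, lv))
  })
  list(curve = curve, lod = unname(lims["lod"]), loq = unname(lims["loq"]),
       controls = do.call(rbind, per_level))
}

#' Assemble a full method-performance report
#'
#' Processes a validation campaign table: per day, an average calibration
#' curve is fitted (replicate sets averaged per level), LOD/LOQ derived
#' from its intercept SD, and the control samples quantified against it
#' for RSD and accuracy. Days tagged `scope == "interday"` are
#' aggregated as the mean of daily values across days; days tagged
#' `"intraday"` summarize repeated sets within one day. The overall row
#' is the mean of the inter- and intra-day outcomes.
#'
#' @param campaign data.frame with columns `scope` (`"interday"` or
#'   `"intraday"`), `day`, `set`, `level_mg_L`, `analyte_area`,
#'   `is_area`, `role` (`"calibrant"` or `"control"`).
#' @return An object of class `performance_report`: `daily` (one row per
#'   scope/day with curve parameters, LOD/LOQ and per-level RSD and
#'   accuracy), `interday`, `intraday` and `overall` summaries.
#' @export
assemble_report <- function(campaign) {
  needed <- c("scope", "day", "set", "level_mg_L", "analyte_area",
              "is_area", "role")
  stopifnot(is.data.frame(campaign), all(needed %in% names(campaign)))
  control_levels <- sort(unique(campaign$level_mg_L[
    campaign$role == "control"]))
  daily_rows <- list()
  for (sc in unique(campaign$scope)) {
    sub <- campaign[campaign$scope == sc, ]
    for (d in sort(unique(sub$day))) {
      res <- daily_performance(sub[sub$day == d, ], control_levels)
      row <- data.frame(
        scope = sc, day = d,
        slope = res$curve$slope, intercept = res$curve$intercept,
        r_squared = res$curve$r_squared, lod = res$lod, loq = res$loq
      )
      for (i in seq_len(nrow(res$controls))) {
        lv <- res$controls$level[i]
        row[[paste0("rsd_", lv)]] <- res$controls$rsd[i]
        row[[paste0("accuracy_", lv)]] <- res$controls$accuracy[i]
      }
      daily_rows[[length(daily_rows) + 1]] <- row
    }
  }
  daily <- do.call(rbind, daily_rows)
  summarize_scope <- function(sc) {
    rows <- daily[daily$scope == sc, ]
    if (nrow(rows) == 0) return(NULL)
    num <- rows[, !(names(rows) %in% c("scope", "day")), drop = FALSE]
    out <- as.data.frame(lapply(num, mean, na.rm = TRUE))
    out$n_days <- nrow(rows)
    out
  }
  interday <- summarize_scope("interday")
  intraday <- summarize_scope("intraday")
  overall <- if (!is.null(interday) && !is.null(intraday)) {
    common <- intersect(names(interday), names(intraday))
    common <- setdiff(common, "n_days")
    as.data.frame(Map(function(a, b) mean(c(a, b)),
                      interday[common], intraday[common]))
  } else {
    x <- interday %||% intraday
    if (!is.null(x)) x[, setdiff(names(x), "n_days"), drop = FALSE]
  }
  structure(list(daily = daily, interday = interday, intraday = intraday,
                 overall = overall, control_levels = control_levels),
            class = "performance_report")
}

#' Rounded display values for a performance report
#'
#' LOD/LOQ to 2 significant figures, percentages to 1 decimal, mirroring
#' how validation tables are conventionally printed.
#'
#' @param report a [assemble_report()] result.
#' @return data.frame of the overall summary with display rounding.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "performance_report"))
  ov <- report$overall
  out <- ov
  for (nm in names(out)) {
    if (nm %in% c("lod", "loq")) {
      out[[nm]] <- signif(out[[nm]], 2)
    } else if (grepl("^(rsd|accuracy)_", nm)) {
      out[[nm]] <- round(out[[nm]], 1)
    } else if (nm == "r_squared") {
      out[[nm]] <- round(out[[nm]], 3)
    }
  }
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Method performance report\n")
  cat("  days:", nrow(x$daily), "(",
      sum(x$daily$scope == "interday"), "inter-day,",
      sum(x$daily$scope == "intraday"), "intra-day )\n")
  cat("  overall (mean of inter- and intra-day):\n")
  print(format_report(x), row.names = FALSE)
  invisible(x)
}
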