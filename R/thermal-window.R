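#' Aggregate rate records into a per-temperature profile
#'
#' QC-passing records are averaged per nominal temperature (sample SD with
#' n-1 denominator); QC-failing records are excluded from the means but
#' counted in the `excluded` attribute so nothing disappears silently.
#' Single-replicate rows report `sd_rate = 0` and carry an `N_EQ_1` flag.
#'
#' @param records Rate-record data frame (see [process_traces()]), or any data
#'   frame with columns `nominal_temperature`, `rate`, `qc_pass`.
#' @return A data frame of class `temperature_profile` with columns
#'   `temperature`, `mean_rate`, `sd_rate`, `n`, `flags`, sorted by
#'   temperature.
#' @export
aggregate_profile <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    abort("no rate records supplied", "empty_input")
  }
  keep <- records[records$qc_pass & is.finite(records$rate), ]
  if (nrow(keep) == 0) {
    abort("no QC-passing rate records to aggregate", "empty_input")
  }
  sp <- split(keep$rate, keep$nominal_temperature)
  prof <- data.frame(
    temperature = as.numeric(names(sp)),
    mean_rate = vapply(sp, mean, numeric(1)),
    sd_rate = vapply(sp, function(x) if (length(x) > 1) sd(x) else 0, numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  prof$flags <- ifelse(prof$n == 1, "N_EQ_1", "")
  prof <- prof[order(prof$temperature), ]
  rownames(prof) <- NULL
  n_excl <- sum(!records$qc_pass | !is.finite(records$rate))
  attr(prof, "excluded") <- n_excl
  class(prof) <- c("temperature_profile", class(prof))
  prof
}

#' Locate the linear aerobic window of a temperature profile
#'
#' Thermal-ramp rate profiles have a characteristic plateau-rise-collapse
#' shape: flat at the temperature-induced standard metabolic rate below the
#' critical cold temperature, rising roughly linearly through the aerobic
#' window, and collapsing beyond the critical warm temperature. The window is
#' located by fitting a continuous three-segment piecewise-linear model
#' (constant / rising line / unconstrained line) for every candidate
#' breakpoint pair on the temperature grid and keeping the pair with the
#' smallest weighted residual sum of squares. Rows are weighted by
#' `n / mean_rate^2`, the right weighting when replicate spread scales with
#' the mean (multiplicative between-animal variation). Candidate windows must
#' span at least `min_span` temperatures, and their interior ordinary
#' least-squares fit of `mean_rate ~ temperature` must have positive slope
#' and R-squared at least `r2_min`; the reported window line is that interior
#' OLS fit. Breakpoints may sit on the profile edges, so a profile with no
#' visible plateau or collapse still yields its maximal linear stretch (the
#' missing downturn is flagged later by [detect_extremes()]).
#'
#' @param profile A [aggregate_profile()] result.
#' @param r2_min Minimum interior R-squared for an acceptable window
#'   (default 0.98).
#' @param min_span Minimum number of grid temperatures inside the window
#'   (default 4).
#' @return An object of class `linear_window` with fields `t_low`, `t_high`,
#'   `slope`, `intercept`, `r_squared`.
#' @export
find_linear_window <- function(profile, r2_min = 0.98, min_span = 4) {
  stopifnot(inherits(profile, "temperature_profile"))
  temps <- profile$temperature
  rates <- profile$mean_rate
  n <- length(temps)
  if (n < min_span) {
    abort(sprintf("profile has %d temperatures; at least min_span = %d required",
                  n, min_span), "no_window")
  }
  w <- profile$n / pmax(rates, .Machine$double.eps)^2
  # SSE comparisons need a scale: near-zero residuals from noiseless input
  # must count as exact ties, not be ranked by floating-point dust
  wsst <- sum(w * (rates - sum(w * rates) / sum(w))^2)
  sse_tol <- 1e-9 * max(wsst, .Machine$double.eps)
  best <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (j - i + 1 < min_span) next
      ct <- temps[i]
      wt <- temps[j]
      # continuous plateau / rise / free segment model, weighted LS
      x1 <- pmax(0, pmin(temps, wt) - ct)
      x2 <- pmax(0, temps - wt)
      X <- cbind(1, x1, x2)
      sw <- sqrt(w)
      segfit <- stats::.lm.fit(X * sw, rates * sw)
      sse <- sum(segfit$residuals^2)
      # interior OLS line: the reported window fit, gated as in the protocol
      inw <- seq(i, j)
      ifit <- stats::.lm.fit(cbind(1, temps[inw]), rates[inw])
      sl <- ifit$coefficients[2]
      sst <- sum((rates[inw] - mean(rates[inw]))^2)
      r2 <- if (sst == 0) 0 else max(0, 1 - sum(ifit$residuals^2) / sst)
      if (!is.finite(sl) || sl <= 0 || r2 < r2_min) next
      width <- wt - ct
      better <- is.null(best) ||
        sse < best$sse - sse_tol ||
        (sse <= best$sse + sse_tol &&
           (width > best$width ||
              (width == best$width && (r2 > best$r_squared ||
                 (r2 == best$r_squared && ct < best$t_low)))))
      if (better) {
        best <- list(t_low = ct, t_high = wt, slope = sl,
                     intercept = ifit$coefficients[1], r_squared = r2,
                     sse = sse, width = width)
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf("no linear window with positive slope and R^2 >= %.3f over >= %d temperatures; consider relaxing r2_min or min_span",
                  r2_min, min_span), "no_window")
  }
  structure(best[c("t_low", "t_high", "slope", "intercept", "r_squared")],
            class = "linear_window")
}

#' @export
print.linear_window <- function(x, ...) {
  cat(sprintf("<linear_window> [%.1f, %.1f] degC, slope %.3f ug/g/h/degC, R^2 %.4f\n",
              x$t_low, x$t_high, x$slope, x$r_squared))
  invisible(x)
}

#' Extract TMMR, TSMR and critical temperatures from a profile
#'
#' The temperature-induced maximal metabolic rate (TMMR) is the mean rate at
#' the warm edge of the linear window, whose temperature is the critical warm
#' temperature `WT_crit`; the temperature-induced standard metabolic rate
#' (TSMR) is the mean rate at the cold edge (`CT_crit`), the onset of the
#' metabolic plateau. Diagnostic warnings (returned, not thrown):
#' `CENSORED_PEAK` when no temperature above `WT_crit` was measured (the
#' downturn was never observed); `NON_PEAK` when some rate above `WT_crit` is
#' not strictly below TMMR; `NO_PLATEAU` when a rate below `CT_crit` deviates
#' from TSMR by more than `plateau_tol`.
#'
#' @param profile A [aggregate_profile()] result.
#' @param window A [find_linear_window()] result.
#' @param plateau_tol Absolute tolerance (ug O2/g/h) for the sub-`CT_crit`
#'   plateau check; defaults to one SD of the `CT_crit` row.
#' @return A list with `TMMR`, `WT_crit`, `TSMR`, `CT_crit` and a character
#'   vector `warnings`.
#' @export
detect_extremes <- function(profile, window, plateau_tol = NULL) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(window, "linear_window"))
  if (window$t_low < min(profile$temperature) ||
      window$t_high > max(profile$temperature)) {
    abort("window lies outside the profile's temperature range", "bad_window")
  }
  row_lo <- profile[profile$temperature == window$t_low, ]
  row_hi <- profile[profile$temperature == window$t_high, ]
  if (nrow(row_lo) != 1 || nrow(row_hi) != 1) {
    abort("window endpoints must sit on profile grid temperatures", "bad_window")
  }
  tmmr <- row_hi$mean_rate
  tsmr <- row_lo$mean_rate
  warnings <- character()
  above <- profile[profile$temperature > window$t_high, ]
  if (nrow(above) == 0) {
    warnings <- c(warnings, "CENSORED_PEAK")
  } else if (any(above$mean_rate >= tmmr)) {
    warnings <- c(warnings, "NON_PEAK")
  }
  below <- profile[profile$temperature < window$t_low, ]
  if (nrow(below)) {
    tol <- if (is.null(plateau_tol)) row_lo$sd_rate else plateau_tol
    if (any(abs(below$mean_rate - tsmr) > tol)) {
      warnings <- c(warnings, "NO_PLATEAU")
    }
  }
  list(TMMR = tmmr, WT_crit = window$t_high, TSMR = tsmr,
       CT_crit = window$t_low, warnings = warnings)
}

#' Temperature-induced aerobic scope
#'
#' The scope is the difference between the temperature-induced maximal and
#' standard metabolic rates, `TAS = TMMR - TSMR` (ug O2/g/h).
#'
#' @param tmmr,tsmr Rates in ug O2/g/h; `tmmr` must be >= `tsmr`.
#' @return The aerobic scope in ug O2/g/h.
#' @export
compute_tas <- function(tmmr, tsmr) {
  if (tmmr < tsmr) {
    abort("TMMR < TSMR: window detection failed upstream", "bad_scope")
  }
  tmmr - tsmr
}

#' Temperature coefficient Q10
#'
#' `Q10 = (r2 / r1) ^ (10 / (t2 - t1))`: the factor by which the rate changes
#' per 10 degC. Symmetric under swapping both endpoints, and invariant to
#' rescaling both rates by the same factor.
#'
#' @param r1,r2 Rates (> 0) at temperatures `t1` and `t2`.
#' @param t1,t2 Temperatures in degC, `t1 != t2`.
#' @return The unitless Q10.
#' @export
compute_q10 <- function(r1, r2, t1, t2) {
  if (r1 <= 0 || r2 <= 0) abort("Q10 requires positive rates", "bad_q10")
  if (t1 == t2) abort("Q10 requires distinct temperatures", "bad_q10")
  (r2 / r1)^(10 / (t2 - t1))
}

#' Midpoint thermal optimum of the aerobic window
#'
#' Halving the aerobic scope gives the rate exactly halfway between TMMR and
#' TSMR, `r_mid = (TMMR + TSMR) / 2`; the temperature at which the window
#' regression attains `r_mid` (clamped to the window) is a geometric thermal
#' optimum: cold- and warm-ward aerobic reserves are equal there. The
#' optimal-performance band spans from the regression rate at the acclimation
#' temperature up to `r_mid`.
#'
#' @param tmmr,tsmr Rates in ug O2/g/h.
#' @param window A [find_linear_window()] result (positive slope).
#' @param acclimation_temperature Acclimation/control temperature in degC
#'   (default 29) anchoring the lower edge of the optimal band.
#' @return A list with `r_mid`, `t_opt`, and `band` (rate and temperature
#'   bounds of the optimal performance range).
#' @export
thermal_optimum <- function(tmmr, tsmr, window, acclimation_temperature = 29) {
  stopifnot(inherits(window, "linear_window"))
  if (window$slope <= 0) abort("window slope must be positive", "bad_window")
  r_mid <- (tmmr + tsmr) / 2
  t_opt <- (r_mid - window$intercept) / window$slope
  t_opt <- min(max(t_opt, window$t_low), window$t_high)
  r_accl <- window$intercept + window$slope * acclimation_temperature
  list(
    r_mid = r_mid, t_opt = t_opt,
    band = list(rate_low = r_accl, rate_high = r_mid,
                t_low = acclimation_temperature, t_high = t_opt)
  )
}

#' Full thermal-window analysis of a set of rate records
#'
#' Aggregates records into a per-temperature profile, locates the linear
#' aerobic window, extracts TMMR/TSMR and the critical temperatures, and
#' derives TAS, the Q10 coefficients between the acclimation temperature and
#' each critical temperature, and the midpoint thermal optimum.
#'
#' @param records Rate-record data frame (see [process_traces()]).
#' @param r2_min,min_span Passed to [find_linear_window()].
#' @param plateau_tol Passed to [detect_extremes()].
#' @param acclimation_temperature Control temperature in degC (default 29);
#'   Q10 endpoints and the optimal band are anchored here.
#' @return An object of class `thermal_window_result`.
#' @export
thermal_window_analysis <- function(records, r2_min = 0.98, min_span = 4,
                                    plateau_tol = NULL,
                                    acclimation_temperature = 29) {
  profile <- aggregate_profile(records)
  window <- find_linear_window(profile, r2_min = r2_min, min_span = min_span)
  ext <- detect_extremes(profile, window, plateau_tol = plateau_tol)
  tas <- compute_tas(ext$TMMR, ext$TSMR)
  ctrl_row <- profile[profile$temperature == acclimation_temperature, ]
  control_rate <- if (nrow(ctrl_row) == 1) ctrl_row$mean_rate else NA_real_
  q10_warm <- if (is.finite(control_rate)) {
    compute_q10(control_rate, ext$TMMR, acclimation_temperature, ext$WT_crit)
  } else NA_real_
  q10_cold <- if (is.finite(control_rate)) {
    compute_q10(control_rate, ext$TSMR, acclimation_temperature, ext$CT_crit)
  } else NA_real_
  opt <- thermal_optimum(ext$TMMR, ext$TSMR, window,
                         acclimation_temperature = acclimation_temperature)
  structure(
    list(TMMR = ext$TMMR, WT_crit = ext$WT_crit, TSMR = ext$TSMR,
         CT_crit = ext$CT_crit, TAS = tas,
         q10_cold = q10_cold, q10_warm = q10_warm,
         control_rate = control_rate,
         acclimation_temperature = acclimation_temperature,
         r_mid = opt$r_mid, t_opt = opt$t_opt, band = opt$band,
         window = window, profile = profile, warnings = ext$warnings),
    class = "thermal_window_result"
  )
}

#' @export
print.thermal_window_result <- function(x, ...) {
  cat("Temperature-induced aerobic scope analysis\n")
  cat(sprintf("  linear window : %.1f-%.1f degC (R^2 = %.3f)\n",
              x$window$t_low, x$window$t_high, x$window$r_squared))
  cat(sprintf("  TSMR          : %6.2f ug O2/g/h at CT_crit = %.1f degC\n",
              x$TSMR, x$CT_crit))
  cat(sprintf("  TMMR          : %6.2f ug O2/g/h at WT_crit = %.1f degC\n",
              x$TMMR, x$WT_crit))
  cat(sprintf("  TAS           : %6.2f ug O2/g/h\n", x$TAS))
  cat(sprintf("  Q10 (%.0f->%.0f degC): %.1f   Q10 (%.0f->%.0f degC): %.1f\n",
              x$acclimation_temperature, x$CT_crit, x$q10_cold,
              x$acclimation_temperature, x$WT_crit, x$q10_warm))
  cat(sprintf("  thermal optimum: %.1f degC at r_mid = %.2f ug O2/g/h\n",
              x$t_opt, x$r_mid))
  if (length(x$warnings)) {
    cat("  warnings      :", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a temperature profile and its aerobic window
#'
#' Base-graphics plot of per-temperature mean rates with SD whiskers, the
#' fitted window line, and dashed markers at TMMR/TSMR.
#'
#' @param x A `thermal_window_result`.
#' @param ... Passed to [plot()].
#' @export
plot.thermal_window_result <- function(x, ...) {
  p <- x$profile
  plot(p$temperature, p$mean_rate, pch = 19,
       xlab = "Temperature (°C)",
       ylab = expression(O[2] ~ consumption ~ (mu * g ~ g^-1 ~ h^-1)), ...)
  arrows(p$temperature, p$mean_rate - p$sd_rate,
         p$temperature, p$mean_rate + p$sd_rate,
         angle = 90, code = 3, length = 0.03)
  tt <- seq(x$window$t_low, x$window$t_high, length.out = 2)
  lines(tt, x$window$intercept + x$window$slope * tt, lwd = 2)
  abline(h = c(x$TSMR, x$TMMR), lty = 3, col = "red")
  abline(v = c(x$CT_crit, x$WT_crit), lty = 3, col = "grey50")
  invisible(x)
}

#' Serialize a thermal-window result to JSON
#'
#' @param x A `thermal_window_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
thermal_window_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "thermal_window_result"))
  payload <- list(
    package_version = as.character(utils::packageVersion("aeroscope")),
    TMMR = x$TMMR, WT_crit = x$WT_crit, TSMR = x$TSMR, CT_crit = x$CT_crit,
    TAS = x$TAS, q10_cold = x$q10_cold, q10_warm = x$q10_warm,
    control_rate = x$control_rate, r_mid = x$r_mid, t_opt = x$t_opt,
    window = list(t_low = x$window$t_low, t_high = x$window$t_high,
                  slope = x$window$slope, intercept = x$window$intercept,
                  r_squared = x$window$r_squared),
    warnings = x$warnings
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
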