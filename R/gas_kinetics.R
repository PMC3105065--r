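#' Parse and validate a three-letter treatment code
#'
#' Microcosm treatments are coded by three factor levels: wetting
#' (`F` flooded / `W` wet-drained), light (`L` light / `D` dark) and
#' headspace (`N` anoxic N2 / `O` oxic air).
#'
#' @param code Character vector of three-letter codes, e.g. `"FDN"`.
#' @return A data.frame with columns `code`, `wetting`, `light`, `headspace`.
#' @examples
#' treatment_code(c("FDN", "WLO"))
#' @export
treatment_code <- function(code) {
  code <- toupper(as.character(code))
  bad <- !grepl("^[FW][LD][NO]$", code)
  if (any(bad)) {
    stop("invalid treatment code(s): ", paste(unique(code[bad]), collapse = ", "),
         " (expected [FW][LD][NO], e.g. \"FDN\")")
  }
  data.frame(
    code = code,
    wetting = substr(code, 1, 1),
    light = substr(code, 2, 2),
    headspace = substr(code, 3, 3),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated headspace gas time series
#'
#' Bundles one microcosm's headspace measurements of a single gas with the
#' physical metadata needed to convert mixing ratios to absolute amounts.
#'
#' @param microcosm_id Identifier of the microcosm.
#' @param treatment Three-letter treatment code (see [treatment_code()]).
#' @param gas One of `"CH4"`, `"CO2"`, `"H2"`, `"O2"`.
#' @param times Sampling times, days since wetting; non-negative, strictly
#'   increasing, length >= 2.
#' @param mixing_ratios Headspace mixing ratios in ppmv, same length as
#'   `times`, all >= 0.
#' @param headspace_ml Headspace volume, mL (> 0). Default 100 mL.
#' @param soil_gdw Soil dry weight, g (> 0). Default 20 g.
#' @param temperature_k Incubation temperature, K. Default 298.15 (25 degC).
#' @param pressure_pa Headspace pressure, Pa. Default 101325.
#' @return An object of class `gas_timeseries`.
#' @export
gas_timeseries <- function(microcosm_id, treatment, gas, times, mixing_ratios,
                           headspace_ml = 100, soil_gdw = 20,
                           temperature_k = 298.15, pressure_pa = 101325) {
  gas <- match.arg(gas, c("CH4", "CO2", "H2", "O2"))
  treatment_code(treatment)
  times <- as.numeric(times)
  mixing_ratios <- as.numeric(mixing_ratios)
  if (length(times) < 2 || length(mixing_ratios) != length(times)) {
    stop("times and mixing_ratios must have equal length >= 2")
  }
  if (any(times < 0)) stop("times must be non-negative (days since wetting)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(mixing_ratios < 0)) stop("mixing_ratios must be >= 0 (ppmv)")
  for (nm in c("headspace_ml", "soil_gdw", "temperature_k", "pressure_pa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single positive number")
    }
  }
  structure(
    list(microcosm_id = as.character(microcosm_id), treatment = treatment,
         gas = gas, times = times, mixing_ratios = mixing_ratios,
         headspace_ml = headspace_ml, soil_gdw = soil_gdw,
         temperature_k = temperature_k, pressure_pa = pressure_pa),
    class = "gas_timeseries"
  )
}

#' @export
print.gas_timeseries <- function(x, ...) {
  cat(sprintf("<gas_timeseries> %s %s [%s]: %d points, day %g-%g\n",
              x$microcosm_id, x$gas, x$treatment, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Convert a headspace mixing ratio to an absolute molar amount
#'
#' Applies the ideal gas law: the amount of the trace gas in the headspace is
#' `ppmv * 1e-6 * P V / (R T)`, reported in nmol.
#'
#' @param ppmv Mixing ratio(s) in ppmv (>= 0).
#' @param volume_ml Headspace volume, mL (> 0).
#' @param temperature_k Temperature, K (> 0). Default 298.15.
#' @param pressure_pa Pressure, Pa (> 0). Default 101325.
#' @return Amount(s) in nmol.
#' @examples
#' mixing_ratio_to_amount(100, 100) # ~408.8 nmol at 25 degC, 1 atm
#' @export
mixing_ratio_to_amount <- function(ppmv, volume_ml, temperature_k = 298.15,
                                   pressure_pa = 101325) {
  if (any(!is.finite(ppmv)) || any(ppmv < 0)) stop("ppmv must be >= 0")
  if (any(volume_ml <= 0) || any(temperature_k <= 0) || any(pressure_pa <= 0)) {
    stop("volume_ml, temperature_k and pressure_pa must all be > 0")
  }
  # total mol in headspace: P[Pa] * V[m3] / (R T); 1 mL = 1e-6 m3; 1 mol = 1e9 nmol
  total_nmol <- pressure_pa * volume_ml * 1e-6 / (.R_GAS * temperature_k) * 1e9
  ppmv * 1e-6 * total_nmol
}

#' Inverse of [mixing_ratio_to_amount()]
#'
#' Converts an absolute headspace amount (nmol) back to a mixing ratio in
#' ppmv. Used by the synthetic-data generator.
#'
#' @inheritParams mixing_ratio_to_amount
#' @param nmol Amount(s) in nmol (>= 0).
#' @return Mixing ratio(s) in ppmv.
#' @export
amount_to_mixing_ratio <- function(nmol, volume_ml, temperature_k = 298.15,
                                   pressure_pa = 101325) {
  if (any(nmol < 0)) stop("nmol must be >= 0")
  nmol / mixing_ratio_to_amount(1, volume_ml, temperature_k, pressure_pa)
}

#' Headspace amounts per gram dry soil
#'
#' Converts every mixing ratio of a [gas_timeseries()] to nmol via the ideal
#' gas law and normalizes by the soil dry weight.
#'
#' @param series A `gas_timeseries` object.
#' @return Numeric vector of amounts in nmol gdw-1, one per time point.
#' @export
amount_per_gdw <- function(series) {
  stopifnot(inherits(series, "gas_timeseries"))
  mixing_ratio_to_amount(series$mixing_ratios, series$headspace_ml,
                         series$temperature_k, series$pressure_pa) / series$soil_gdw
}

#' Estimate a gas production rate by linear regression
#'
#' Ordinary least squares of amount against time, restricted to a time
#' window. The intercept is free (not forced through the origin): early-lag
#' offsets do not bias the slope. Rates may be negative (e.g. O2 consumption).
#'
#' @param times Sampling times, days.
#' @param amounts Amounts in nmol gdw-1, same length as `times`.
#' @param window Numeric length-2, `c(day_start, day_end)` inclusive. Default
#'   covers the full series.
#' @return An object of class `rate_estimate`: a list with `rate` (nmol gdw-1
#'   d-1), `standard_error`, `r_squared`, `n_points` and `window`.
#' @examples
#' estimate_production_rate(c(0, 7, 14, 21), c(0, 700, 1400, 2100))
#' @export
estimate_production_rate <- function(times, amounts, window = range(times)) {
  if (length(times) != length(amounts)) stop("times and amounts lengths differ")
  keep <- is.finite(times) & is.finite(amounts) &
    times >= window[1] & times <= window[2]
  x <- times[keep]
  y <- amounts[keep]
  if (length(x) < 2) {
    stop("insufficient data: fewer than 2 points inside window [",
         window[1], ", ", window[2], "]")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  n <- length(x)
  res <- fit$residuals
  sxx <- sum((x - mean(x))^2)
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - sum(res^2) / syy else NA_real_
  structure(
    list(rate = slope, standard_error = se, r_squared = r2,
         n_points = n, window = as.numeric(window)),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %.4g nmol gdw-1 d-1 (SE %.3g, r2 %.4f, n = %d, days %g-%g)\n",
    x$rate, x$standard_error, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Fit production rates for every microcosm in a gas table
#'
#' Splits a long-format gas table (see [read_gas_table()]) by microcosm and
#' gas, converts to nmol gdw-1 and regresses against time.
#'
#' @param gas_table Data frame with columns `microcosm_id`, `treatment`,
#'   `gas`, `day`, `ppmv`, `headspace_ml`, `soil_gdw`, `temp_k`, `pressure_pa`.
#' @param window Regression window in days, default `c(0, 42)` (the full
#'   incubation). `c(14, 42)` excludes the activation lag.
#' @param gas Which gas to fit. Default `"CH4"`.
#' @return Data frame with one row per microcosm: `microcosm_id`, `treatment`,
#'   `gas`, `rate`, `standard_error`, `r_squared`, `n_points`.
#' @export
fit_rates <- function(gas_table, window = c(0, 42), gas = "CH4") {
  tab <- gas_table[gas_table$gas == gas, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for gas ", gas)
  out <- lapply(split(tab, tab$microcosm_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    ts <- gas_timeseries(d$microcosm_id[1], d$treatment[1], gas,
                         d$day, d$ppmv, d$headspace_ml[1], d$soil_gdw[1],
                         d$temp_k[1], d$pressure_pa[1])
    est <- estimate_production_rate(ts$times, amount_per_gdw(ts), window)
    data.frame(microcosm_id = d$microcosm_id[1], treatment = d$treatment[1],
               gas = gas, rate = est$rate, standard_error = est$standard_error,
               r_squared = est$r_squared, n_points = est$n_points,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize replicate rates per treatment
#'
#' Arithmetic mean and standard error (sd/sqrt(n)) of replicate rate
#' estimates within each treatment. A single replicate yields `NA` SE.
#'
#' @param rates Data frame with columns `treatment` and `rate` (one row per
#'   microcosm), e.g. the output of [fit_rates()].
#' @return Data frame with columns `treatment`, `mean_rate`, `se_rate`, `n`.
#' @export
summarize_rates <- function(rates) {
  if (nrow(rates) == 0) stop("empty rate table")
  groups <- split(rates$rate, rates$treatment)
  out <- do.call(rbind, lapply(names(groups), function(tr) {
    r <- groups[[tr]]
    if (length(r) == 0) stop("empty replicate group for treatment ", tr)
    data.frame(treatment = tr, mean_rate = mean(r),
               se_rate = if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_,
               n = length(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
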