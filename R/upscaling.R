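# Upscaling per-gram methane production rates to areal annual emission and
# a global desert source term.

#' Areal annual methane emission from a per-gram rate
#'
#' Converts a crust production rate (nmol CH4 per gram dry crust per day)
#' into an areal annual emission assuming the crust is methanogenically
#' active only while wet:
#' `rate * wet_weeks * 7 * crust_areal_density * molar_mass * 1e-6`
#' (the 1e-6 converts nmol to mg via g mol-1).
#'
#' @param rate CH4 production rate, nmol gdw-1 d-1.
#' @param wet_weeks Weeks per year the crust is wet and active (2-7 for
#'   arid-region crusts).
#' @param crust_areal_density Dry crust mass per unit area, g m-2. Default
#'   5300 (a 3-4 mm crust at silty-loam bulk density).
#' @param molar_mass Molar mass of CH4, g mol-1. Default 16.04.
#' @return Areal emission, mg CH4 m-2 yr-1.
#' @examples
#' areal_rate(21.7, 7) # ~90 mg m-2 yr-1
#' @export
areal_rate <- function(rate, wet_weeks, crust_areal_density = 5300,
                       molar_mass = 16.04) {
  if (any(c(wet_weeks, crust_areal_density, molar_mass) <= 0)) {
    stop("wet_weeks, crust_areal_density and molar_mass must be > 0")
  }
  rate * (wet_weeks * 7) * crust_areal_density * molar_mass * 1e-6
}

#' Global desert methane source from an areal emission
#'
#' `areal_rate_mg_m2_yr * desert_area_km2 * 1e6 m2/km2 * 1e-15 Tg/mg`.
#'
#' @param areal_rate_mg_m2_yr Areal emission, mg CH4 m-2 yr-1.
#' @param desert_area_km2 Area of deserts, km2. Default 44e6 (semiarid,
#'   arid and hyperarid regions combined).
#' @return Global source, Tg CH4 yr-1.
#' @examples
#' global_source(26)  # ~1.1 Tg yr-1
#' global_source(92)  # ~4.0 Tg yr-1
#' @export
global_source <- function(areal_rate_mg_m2_yr, desert_area_km2 = 44e6) {
  if (any(desert_area_km2 < 0)) stop("desert_area_km2 must be >= 0")
  areal_rate_mg_m2_yr * desert_area_km2 * 1e6 * 1e-15
}

#' Scenario grid of areal and global emission estimates
#'
#' Evaluates [areal_rate()] and [global_source()] over all combinations of
#' rates and wet-week scenarios.
#'
#' @inheritParams areal_rate
#' @inheritParams global_source
#' @param rates Named or unnamed vector of rates, nmol gdw-1 d-1.
#' @param wet_weeks Vector of wet-week scenarios.
#' @return Data frame with `rate`, `wet_weeks`, `areal_mg_m2_yr`,
#'   `global_tg_yr`.
#' @export
upscale_grid <- function(rates, wet_weeks = c(2, 7),
                         crust_areal_density = 5300, molar_mass = 16.04,
                         desert_area_km2 = 44e6) {
  g <- expand.grid(rate = rates, wet_weeks = wet_weeks)
  g$areal_mg_m2_yr <- areal_rate(g$rate, g$wet_weeks, crust_areal_density,
                                 molar_mass)
  g$global_tg_yr <- global_source(g$areal_mg_m2_yr, desert_area_km2)
  g
}
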