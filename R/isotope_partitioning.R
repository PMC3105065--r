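# Stable carbon isotope calculus for methanogenic pathway partitioning.
#
# Conventions: all delta values are delta13C in permil vs V-PDB, bounded
# below by -1000 permil (the physical limit of the delta scale). The
# apparent fractionation factor alpha relates CO2 and CH4 as
# alpha = (dCO2 + 1000) / (dCH4 + 1000), and epsilon = (alpha - 1) * 1000.

.check_delta <- function(..., what = "delta") {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= -1000)) {
    stop(what, " values must be finite and > -1000 permil")
  }
  invisible(v)
}

#' Fraction of newly formed methane between two time points
#'
#' In an accumulating (closed) headspace, the methane present at time 2 is a
#' mixture of the pool already present at time 1 and the newly formed
#' methane; the new fraction is `(amount2 - amount1) / amount2`.
#'
#' @param amount1,amount2 CH4 amounts (any consistent unit, e.g. nmol gdw-1)
#'   at the earlier and later time point; requires `amount2 > amount1 >= 0`.
#' @return Fraction in (0, 1].
#' @examples
#' fraction_new(100, 400) # 0.75
#' @export
fraction_new <- function(amount1, amount2) {
  if (any(amount1 < 0)) stop("amount1 must be >= 0")
  if (any(amount2 <= amount1)) {
    stop("no net production: amount2 must exceed amount1 in the interval")
  }
  (amount2 - amount1) / amount2
}

#' Isotopic signature of the newly formed methane
#'
#' Two-pool mass balance: the pool at time 2 mixes the old pool (signature
#' `delta1`, fraction `1 - fraction_new`) with the new methane (signature
#' `delta_n`), so `delta_n = (delta2 - (1 - fn) * delta1) / fn`.
#'
#' @param delta1,delta2 delta13C-CH4 (permil vs V-PDB) at times 1 and 2.
#' @param fraction_new Fraction of new methane at time 2, in (0, 1]
#'   (see [fraction_new()]).
#' @return delta13C of the newly formed methane, permil.
#' @examples
#' newly_formed_delta(-60, -50, 0.5) # -40
#' @export
newly_formed_delta <- function(delta1, delta2, fraction_new) {
  .check_delta(delta1, delta2)
  if (any(fraction_new <= 0) || any(fraction_new > 1)) {
    stop("fraction_new must lie in (0, 1]")
  }
  (delta2 - (1 - fraction_new) * delta1) / fraction_new
}

#' Apparent CO2 -> CH4 fractionation factor
#'
#' `alpha_app = (delta_CO2 + 1000) / (delta_CH4 + 1000)`. Values near
#' 1.040-1.080 are diagnostic of hydrogenotrophic methanogenesis, values
#' near 1.02-1.03 of acetoclastic methanogenesis.
#'
#' @param delta_co2,delta_ch4 delta13C (permil vs V-PDB) of headspace CO2
#'   and CH4 at the same time point.
#' @return List of class `fractionation_result` with `alpha_app` and
#'   `epsilon_app` (permil).
#' @examples
#' apparent_fractionation(-11.5, -35) # alpha ~ 1.0244
#' @export
apparent_fractionation <- function(delta_co2, delta_ch4) {
  .check_delta(delta_co2, delta_ch4)
  alpha <- (delta_co2 + 1000) / (delta_ch4 + 1000)
  structure(list(alpha_app = alpha, epsilon_app = alpha_to_epsilon(alpha)),
            class = "fractionation_result")
}

#' @export
print.fractionation_result <- function(x, ...) {
  cat(sprintf("<fractionation> alpha_app = %.4f (epsilon_app = %.2f permil)\n",
              x$alpha_app[1], x$epsilon_app[1]))
  invisible(x)
}

#' Convert between alpha and epsilon fractionation notation
#'
#' `epsilon = (alpha - 1) * 1000` and its inverse; the round trip is exact.
#'
#' @param alpha Fractionation factor (> 0, dimensionless).
#' @param epsilon Fractionation in permil.
#' @return The converted value.
#' @export
alpha_to_epsilon <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  (alpha - 1) * 1000
}

#' @rdname alpha_to_epsilon
#' @export
epsilon_to_alpha <- function(epsilon) {
  epsilon / 1000 + 1
}

#' delta13C of acetoclastically produced methane
#'
#' The acetoclastic end member is estimated from the soil organic carbon
#' signature, assuming negligible fractionation from organic C to acetate
#' and a configurable acetate-to-methane fractionation (0 or -25.6 permil in
#' the standard scenarios).
#'
#' @param delta_organic delta13C of soil organic carbon, permil.
#' @param acetate_to_methane_fractionation Fractionation applied during
#'   acetate cleavage, permil (<= 0 in the standard scenarios).
#' @return delta_ma, permil.
#' @examples
#' acetate_endmember(-20.5, -25.6) # -46.1
#' @export
acetate_endmember <- function(delta_organic, acetate_to_methane_fractionation = 0) {
  delta_organic + acetate_to_methane_fractionation
}

#' Partition methane between hydrogenotrophic and acetoclastic pathways
#'
#' Linear two-end-member mixing: the hydrogenotrophic fraction is
#' `f_mc = (delta_CH4 - delta_ma) / (delta_mc - delta_ma)`, with `delta_ma`
#' the purely acetoclastic and `delta_mc` the purely hydrogenotrophic
#' signature. Raw values outside \[0, 1\] (measurement lying outside the
#' end-member interval) are clamped and flagged; the raw value is retained
#' for diagnostics.
#'
#' @param delta_ch4 Observed delta13C-CH4, permil.
#' @param delta_ma Acetoclastic end member, permil (see
#'   [acetate_endmember()]).
#' @param delta_mc Hydrogenotrophic end member, permil (e.g. from a CH3F
#'   inhibition calibration, or the oxic/oxygenic microcosm mean).
#' @return List of class `pathway_partition` with `f_hydrogenotrophic`,
#'   `f_acetoclastic`, `raw_f_hydrogenotrophic`, `clamped`, `delta_ma`,
#'   `delta_mc`.
#' @examples
#' partition_pathways(-35, -20.5, -75) # f_ac ~ 0.734
#' @export
partition_pathways <- function(delta_ch4, delta_ma, delta_mc) {
  .check_delta(delta_ch4, delta_ma, delta_mc)
  if (any(delta_ma == delta_mc)) {
    stop("degenerate end members: delta_ma and delta_mc must differ")
  }
  raw <- (delta_ch4 - delta_ma) / (delta_mc - delta_ma)
  f_mc <- pmin(pmax(raw, 0), 1)
  structure(
    list(f_hydrogenotrophic = f_mc, f_acetoclastic = 1 - f_mc,
         raw_f_hydrogenotrophic = raw, clamped = raw < 0 | raw > 1,
         delta_ma = delta_ma, delta_mc = delta_mc),
    class = "pathway_partition"
  )
}

#' @export
print.pathway_partition <- function(x, ...) {
  cat(sprintf(
    "<pathway_partition> f_H2/CO2 = %.3f, f_acetate = %.3f%s (end members %.4g / %.4g permil)\n",
    x$f_hydrogenotrophic[1], x$f_acetoclastic[1],
    if (any(x$clamped)) " [clamped]" else "", x$delta_ma[1], x$delta_mc[1]))
  invisible(x)
}

#' Pathway partition with first-order (delta-method) uncertainty
#'
#' Propagates standard errors of the three delta values through the linear
#' mixing formula. With `f = (x - a) / (c - a)` for `x = delta_ch4`,
#' `a = delta_ma`, `c = delta_mc`, the gradient is `(1/(c-a),
#' (x-c)/(c-a)^2, -(x-a)/(c-a)^2)` and the SE is the quadrature sum.
#' The SE refers to the raw (unclamped) fraction.
#'
#' @inheritParams partition_pathways
#' @param se_ch4,se_ma,se_mc Standard errors of the deltas, permil (>= 0).
#' @return A `pathway_partition` with an additional `standard_error` field.
#' @export
partition_with_uncertainty <- function(delta_ch4, delta_ma, delta_mc,
                                       se_ch4 = 0, se_ma = 0, se_mc = 0) {
  if (any(c(se_ch4, se_ma, se_mc) < 0)) stop("standard errors must be >= 0")
  part <- partition_pathways(delta_ch4, delta_ma, delta_mc)
  d <- delta_mc - delta_ma
  g_x <- 1 / d
  g_a <- (delta_ch4 - delta_mc) / d^2
  g_c <- -(delta_ch4 - delta_ma) / d^2
  part$standard_error <- sqrt((g_x * se_ch4)^2 + (g_a * se_ma)^2 + (g_c * se_mc)^2)
  part
}

#' Carbonate-derived fraction of headspace CO2
#'
#' Two-pool mixing between the organic-carbon and carbonate end members:
#' `f_carb = (delta_CO2 - delta_organic) / (delta_carbonate - delta_organic)`,
#' clamped to \[0, 1\] with a flag.
#'
#' @param delta_co2 Observed delta13C-CO2, permil.
#' @param delta_organic,delta_carbonate End members, permil (must differ).
#' @return List with `fraction_carbonate`, `raw_fraction`, `clamped`.
#' @examples
#' co2_source_fraction(-11.5, -20.5, -4.09) # ~0.548 from carbonate
#' @export
co2_source_fraction <- function(delta_co2, delta_organic = -20.5,
                                delta_carbonate = -4.09) {
  .check_delta(delta_co2, delta_organic, delta_carbonate)
  if (any(delta_organic == delta_carbonate)) {
    stop("degenerate end members: delta_organic and delta_carbonate must differ")
  }
  raw <- (delta_co2 - delta_organic) / (delta_carbonate - delta_organic)
  list(fraction_carbonate = pmin(pmax(raw, 0), 1), raw_fraction = raw,
       clamped = raw < 0 | raw > 1)
}

#' Newly-formed methane signatures along an isotope time series
#'
#' Applies [fraction_new()] and [newly_formed_delta()] to successive pairs
#' of points. Intervals without net production are skipped with a warning.
#'
#' @param iso Data frame with columns `day`, `delta_ch4`, `ch4_nmol_gdw`
#'   (one microcosm, ordered or orderable by day).
#' @return Data frame with columns `day_start`, `day_end`, `fraction_new`,
#'   `delta_new`.
#' @export
new_methane_series <- function(iso) {
  iso <- iso[order(iso$day), , drop = FALSE]
  n <- nrow(iso)
  if (n < 2) stop("need at least two isotope points")
  rows <- list()
  for (i in seq_len(n - 1)) {
    a1 <- iso$ch4_nmol_gdw[i]; a2 <- iso$ch4_nmol_gdw[i + 1]
    if (a2 <= a1) {
      warning(sprintf("no net CH4 production in interval day %g-%g; skipped",
                      iso$day[i], iso$day[i + 1]))
      next
    }
    fn <- fraction_new(a1, a2)
    rows[[length(rows) + 1]] <- data.frame(
      day_start = iso$day[i], day_end = iso$day[i + 1], fraction_new = fn,
      delta_new = newly_formed_delta(iso$delta_ch4[i], iso$delta_ch4[i + 1], fn))
  }
  if (length(rows) == 0) stop("no intervals with net CH4 production")
  do.call(rbind, rows)
}
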