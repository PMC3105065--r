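# Steady-state diffusion-reaction modelling of oxygen microprofiles.
#
# The crust is treated as a 1-D porous medium with piecewise-constant
# volumetric net production P(z) (negative = consumption). At steady state
#   d/dz (phi * Ds * dC/dz) + P(z) = 0
# with a fixed concentration at the top of the profile and zero flux at the
# bottom (closed microcosm). The solution is piecewise quadratic and C1
# continuous across zone boundaries, so fluxes follow analytically from
# Fick's first law.
#
# Unit bookkeeping: depths are um (positive downward), concentrations
# umol L-1 (identically nmol cm-3), rates nmol cm-3 s-1, diffusivity m2 s-1
# (converted internally to cm2 s-1), fluxes nmol cm-2 s-1.

.UM_PER_CM <- 1e4

#' Construct a validated oxygen microprofile
#'
#' @param depths_um Measurement depths, um from the crust surface, positive
#'   downward, strictly increasing; at least 4 points.
#' @param concentrations O2 concentrations, umol L-1 (>= 0), same length.
#' @param porosity Volume fraction available for diffusion, in (0, 1].
#'   Default 0.6 (water-saturated silty loam).
#' @param diffusivity Effective sediment diffusion coefficient Ds, m2 s-1.
#'   Default 1.2e-9 (O2 in a water-saturated silty loam at 25 degC).
#' @return Object of class `o2_profile`.
#' @export
o2_profile <- function(depths_um, concentrations, porosity = 0.6,
                       diffusivity = 1.2e-9) {
  depths_um <- as.numeric(depths_um)
  concentrations <- as.numeric(concentrations)
  if (length(depths_um) < 4 || length(concentrations) != length(depths_um)) {
    stop("need >= 4 depth/concentration pairs of equal length")
  }
  if (any(diff(depths_um) <= 0)) stop("depths must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0 (umol L-1)")
  if (porosity <= 0 || porosity > 1) stop("porosity must lie in (0, 1]")
  if (diffusivity <= 0) stop("diffusivity must be > 0 (m2 s-1)")
  structure(list(depths_um = depths_um, concentrations = concentrations,
                 porosity = porosity, diffusivity = diffusivity),
            class = "o2_profile")
}

#' @export
print.o2_profile <- function(x, ...) {
  cat(sprintf("<o2_profile> %d points, %g-%g um, C(top) = %g umol L-1\n",
              length(x$depths_um), min(x$depths_um), max(x$depths_um),
              x$concentrations[1]))
  invisible(x)
}

#' Forward-model a steady-state oxygen profile
#'
#' Solves the steady-state diffusion-reaction balance for piecewise-constant
#' zone rates with a Dirichlet condition at the top boundary and zero flux
#' at the bottom. The analytic solution is quadratic within each zone and
#' C1-continuous at zone boundaries.
#'
#' @param zone_boundaries_um Zone edges, um: length `n_zones + 1`, strictly
#'   increasing, spanning the modelled depth interval (first edge = top of
#'   the grid, last = bottom).
#' @param zone_rates Net volumetric production per zone, nmol cm-3 s-1
#'   (negative = consumption); length `n_zones`.
#' @param top_concentration Concentration fixed at the top edge, umol L-1.
#' @param porosity,diffusivity Transport parameters (see [o2_profile()]).
#' @param depth_grid_um Depths at which to evaluate the solution, um; must
#'   lie within the zone span.
#' @return Object of class `o2_forward`: `depths_um`, `concentrations`,
#'   `zone_boundaries_um`, `zone_rates`, `surface_flux` (nmol cm-2 s-1,
#'   positive into the soil), and `nonphysical` (TRUE if the solution goes
#'   negative anywhere - flagged, not an error).
#' @examples
#' fw <- forward_profile(c(0, 1000, 2500), c(-2, -1), 250,
#'                       depth_grid_um = seq(0, 2500, 100),
#'                       diffusivity = 2e-6)
#' surface_flux(fw)
#' @export
forward_profile <- function(zone_boundaries_um, zone_rates, top_concentration,
                            porosity = 0.6, diffusivity = 1.2e-9,
                            depth_grid_um = NULL) {
  b <- as.numeric(zone_boundaries_um)
  P <- as.numeric(zone_rates)
  if (length(b) != length(P) + 1) {
    stop("zone_boundaries_um must have length(zone_rates) + 1 edges")
  }
  if (any(diff(b) <= 0)) stop("zone boundaries must be strictly increasing")
  if (top_concentration < 0) stop("top_concentration must be >= 0")
  if (is.null(depth_grid_um)) depth_grid_um <- seq(b[1], b[length(b)], length.out = 101)
  z <- as.numeric(depth_grid_um)
  if (min(z) < b[1] - 1e-9 || max(z) > b[length(b)] + 1e-9) {
    stop("depth_grid_um must lie within the zone span")
  }

  D <- porosity * diffusivity * 1e4            # effective phi*Ds, cm2 s-1
  b_cm <- b / .UM_PER_CM
  z_cm <- z / .UM_PER_CM
  thick <- diff(b_cm)
  k <- length(P)

  # u(z) = phi*Ds*dC/dz; u(bottom) = 0, du/dz = -P
  u_b <- c(rev(cumsum(rev(P * thick))), 0)      # u at each boundary, length k+1
  int_u <- u_b[-1] * thick + P * thick^2 / 2    # integral of u over each zone
  C_b <- top_concentration + cumsum(c(0, int_u)) / D

  zone_of <- pmin(pmax(findInterval(z_cm, b_cm, rightmost.closed = TRUE), 1), k)
  j <- zone_of
  conc <- C_b[j] + (u_b[j + 1] * (z_cm - b_cm[j]) +
                      P[j] * (thick[j]^2 - (b_cm[j + 1] - z_cm)^2) / 2) / D

  structure(
    list(depths_um = z, concentrations = conc, zone_boundaries_um = b,
         zone_rates = P, porosity = porosity, diffusivity = diffusivity,
         top_concentration = top_concentration,
         surface_flux = -sum(P * thick),
         nonphysical = any(conc < -1e-9)),
    class = "o2_forward"
  )
}

#' @export
print.o2_forward <- function(x, ...) {
  cat(sprintf(
    "<o2_forward> %d zones over %g-%g um, surface flux %.4g nmol cm-2 s-1%s\n",
    length(x$zone_rates), min(x$zone_boundaries_um), max(x$zone_boundaries_um),
    x$surface_flux, if (x$nonphysical) " [non-physical: C < 0]" else ""))
  invisible(x)
}

#' Diffusive oxygen flux across the crust surface
#'
#' Fick's first law at the top of the profile, `J = -phi * Ds * dC/dz`,
#' with the convention that a positive flux is directed into the soil.
#' For forward solutions and zone fits the analytic derivative of the
#' piecewise-quadratic solution is used (equivalently, conservation:
#' `J = -sum(zone_rate * zone_thickness)`). For a raw numeric profile the
#' gradient over the two shallowest points is used.
#'
#' @param x An `o2_forward`, `profile_fit`, or numeric concentration vector.
#' @param ... Further arguments; for the numeric method, `depths_um`,
#'   `porosity`, `diffusivity`.
#' @return Flux in nmol cm-2 s-1 (positive into the soil).
#' @export
surface_flux <- function(x, ...) UseMethod("surface_flux")

#' @export
surface_flux.o2_forward <- function(x, ...) x$surface_flux

#' @export
surface_flux.profile_fit <- function(x, ...) x$surface_flux

#' @rdname surface_flux
#' @param depths_um Depths, um (numeric method only).
#' @param porosity,diffusivity Transport parameters (numeric method only).
#' @export
surface_flux.numeric <- function(x, depths_um, porosity = 0.6,
                                 diffusivity = 1.2e-9, ...) {
  if (length(x) < 2 || length(depths_um) != length(x)) {
    stop("need >= 2 concentrations with matching depths")
  }
  grad_cm <- (x[2] - x[1]) / ((depths_um[2] - depths_um[1]) / .UM_PER_CM)
  -porosity * diffusivity * 1e4 * grad_cm
}

# Response basis for the linear inverse problem: column j is the forward
# solution for a unit rate in zone j (top concentration 0), evaluated at the
# measurement depths.
.zone_basis <- function(boundaries_um, depths_um, porosity, diffusivity) {
  k <- length(boundaries_um) - 1
  vapply(seq_len(k), function(j) {
    rates <- numeric(k); rates[j] <- 1
    forward_profile(boundaries_um, rates, top_concentration = 0,
                    porosity = porosity, diffusivity = diffusivity,
                    depth_grid_um = depths_um)$concentrations
  }, numeric(length(depths_um)))
}

# Best least-squares rates for fixed boundaries; returns rates and SSE.
.fit_fixed_boundaries <- function(boundaries_um, depths_um, y, C0,
                                  porosity, diffusivity) {
  B <- .zone_basis(boundaries_um, depths_um, porosity, diffusivity)
  fit <- lm.fit(B, y - C0)
  list(rates = unname(fit$coefficients), sse = sum(fit$residuals^2))
}

#' Invert an oxygen profile into production/consumption zones
#'
#' Least-squares inversion of a measured microprofile into k
#' piecewise-constant volumetric rate zones (the linear sub-problem is
#' solved exactly for each candidate zone geometry; zone boundaries are
#' searched exhaustively over the measurement depths). The zone count is
#' selected by nested F-tests: the smallest k is accepted for which adding
#' a further zone does not significantly reduce the residual sum of squares
#' at level `alpha`.
#'
#' The concentration measured at the shallowest depth serves as the fixed
#' top boundary condition; the bottom boundary is zero flux.
#'
#' @param profile An [o2_profile()] object.
#' @param max_zones Maximum number of zones to consider (>= 1). Default 3.
#' @param alpha Significance level of the nested F-test. Default 0.05.
#' @param min_intervals Minimum number of measurement intervals a zone must
#'   span (default 2). Zones thinner than this are underdetermined - their
#'   rate is constrained by at most one interior point and can blow up
#'   under measurement noise - so such candidate geometries are excluded.
#' @return Object of class `profile_fit`: `zone_boundaries_um` (edges),
#'   `zone_rates` (nmol cm-3 s-1, negative = consumption), `surface_flux`
#'   (nmol cm-2 s-1), `sse`, `n_zones`, `selection_pvalue` (F-test p for
#'   accepting this k against k+1; NA when k = max_zones or the fit is
#'   already exact), `fitted` (concentrations at the measured depths),
#'   `sse_by_k` (best SSE per candidate k).
#' @export
fit_production_zones <- function(profile, max_zones = 3, alpha = 0.05,
                                 min_intervals = 2) {
  stopifnot(inherits(profile, "o2_profile"))
  if (max_zones < 1) stop("max_zones must be >= 1")
  z <- profile$depths_um
  y <- profile$concentrations
  n <- length(z)
  if (n <= max_zones + 1) stop("not enough points: need n_points > n_zones + 1")
  C0 <- y[1]
  top <- z[1]; bottom <- z[n]
  interior <- z[-c(1, n)]

  best <- vector("list", max_zones)
  for (k in seq_len(max_zones)) {
    if (k == 1) {
      cand <- list(numeric(0))
    } else {
      if (length(interior) < k - 1) break
      cm <- combn(interior, k - 1)
      cand <- lapply(seq_len(ncol(cm)), function(i) cm[, i])
    }
    for (cuts in cand) {
      bnd <- c(top, cuts, bottom)
      # each zone must contain at least min_intervals measurement intervals
      n_iv <- vapply(seq_len(length(bnd) - 1), function(j) {
        sum(z > bnd[j] & z <= bnd[j + 1])
      }, numeric(1))
      if (any(n_iv < min_intervals)) next
      f <- .fit_fixed_boundaries(bnd, z, y, C0, profile$porosity,
                                 profile$diffusivity)
      if (is.null(best[[k]]) || f$sse < best[[k]]$sse) {
        best[[k]] <- c(f, list(boundaries = bnd))
      }
    }
  }
  best <- best[!vapply(best, is.null, logical(1))]
  kmax <- length(best)
  sse_by_k <- vapply(best, `[[`, numeric(1), "sse")

  # model df: k rates + (k-1) interior boundaries
  p_of <- function(k) 2 * k - 1
  syy <- sum((y - mean(y))^2)
  tol <- max(syy, 1) * 1e-12

  selected <- kmax
  sel_p <- NA_real_
  for (k in seq_len(kmax)) {
    if (k == kmax || sse_by_k[k] <= tol) { selected <- k; break }
    df2 <- n - p_of(k + 1)
    dp <- p_of(k + 1) - p_of(k)
    if (df2 <= 0) { selected <- k; break }
    if (sse_by_k[k + 1] <= tol) {
      # next fit is exact while this one is not: take the larger model
      next
    }
    Fstat <- ((sse_by_k[k] - sse_by_k[k + 1]) / dp) / (sse_by_k[k + 1] / df2)
    pval <- pf(max(Fstat, 0), dp, df2, lower.tail = FALSE)
    if (pval >= alpha) { selected <- k; sel_p <- pval; break }
  }

  bf <- best[[selected]]
  thick_cm <- diff(bf$boundaries) / .UM_PER_CM
  fitted <- C0 + .zone_basis(bf$boundaries, z, profile$porosity,
                             profile$diffusivity) %*% bf$rates
  structure(
    list(zone_boundaries_um = bf$boundaries, zone_rates = bf$rates,
         surface_flux = -sum(bf$rates * thick_cm), sse = bf$sse,
         n_zones = selected, selection_pvalue = sel_p,
         fitted = as.numeric(fitted), sse_by_k = sse_by_k,
         porosity = profile$porosity, diffusivity = profile$diffusivity,
         nonphysical = any(fitted < -1e-9 & y >= 0)),
    class = "profile_fit"
  )
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "<profile_fit> k = %d zones, flux %.4g nmol cm-2 s-1, SSE %.4g%s\n",
    x$n_zones, x$surface_flux, x$sse,
    if (isTRUE(x$nonphysical)) " [fit dips below 0]" else ""))
  cat("  rates (nmol cm-3 s-1):", signif(x$zone_rates, 4), "\n")
  invisible(x)
}

#' Anoxic boundary depth of a profile
#'
#' The shallowest depth below which the O2 concentration stays under
#' `threshold_fraction` of the air-saturation concentration for all deeper
#' measurements, located by linear interpolation between the bracketing
#' points. Profiles that never drop below the threshold are flagged
#' `reached = FALSE`.
#'
#' @param profile An [o2_profile()] object, or a numeric concentration
#'   vector (then supply `depths_um`).
#' @param air_saturation Air-saturation O2 concentration, umol L-1 (> 0).
#'   Default 250 (freshwater at 25 degC).
#' @param threshold_fraction Fraction of `air_saturation` defining "anoxic".
#'   Default 0.01 (the 1 percent criterion).
#' @param depths_um Depths, um (only when `profile` is a bare vector).
#' @return List with `depth_um` (NA when not reached), `reached`,
#'   `threshold_umol_l`.
#' @export
anoxic_boundary <- function(profile, air_saturation = 250,
                            threshold_fraction = 0.01, depths_um = NULL) {
  if (inherits(profile, "o2_profile")) {
    z <- profile$depths_um; conc <- profile$concentrations
  } else {
    conc <- as.numeric(profile); z <- as.numeric(depths_um)
    if (length(z) != length(conc)) stop("depths_um must match concentrations")
  }
  if (air_saturation <= 0) stop("air_saturation must be > 0")
  thr <- threshold_fraction * air_saturation
  below <- conc < thr
  # first index from which all deeper measurements are below threshold
  idx <- which(below & rev(cumprod(rev(below))) == 1)
  if (length(idx) == 0) {
    return(list(depth_um = NA_real_, reached = FALSE, threshold_umol_l = thr))
  }
  i <- min(idx)
  if (i == 1 || conc[i] == thr) {
    d <- z[i]
  } else {
    # interpolate the crossing between the bracketing measurements
    d <- z[i - 1] + (thr - conc[i - 1]) / (conc[i] - conc[i - 1]) * (z[i] - z[i - 1])
  }
  list(depth_um = d, reached = TRUE, threshold_umol_l = thr)
}
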