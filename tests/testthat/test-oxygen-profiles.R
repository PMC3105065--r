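# Scenario shared by several tests: two consumption zones whose integrated
# consumption equals a 10 nmol cm-2 s-1 surface influx, decaying from
# air-equilibrated water at the surface to near-anoxia at 2.5 mm.
o2_scenario <- list(boundaries = c(0, 1000, 2500), rates = c(-70, -20),
                    top = 250, porosity = 0.6, diffusivity = 6e-7,
                    grid = seq(0, 2500, 100))

test_that("forward model honours trivial and conservation limits", {
  # no reaction: constant profile, zero flux
  fw0 <- forward_profile(c(0, 2000), 0, 210, depth_grid_um = seq(0, 2000, 100))
  expect_equal(fw0$concentrations, rep(210, 21))
  expect_equal(surface_flux(fw0), 0)
  # single consumption zone R over total depth L: influx = R*L
  fw1 <- forward_profile(c(0, 2500), -40, 250, porosity = 0.6,
                         diffusivity = 2e-6, depth_grid_um = seq(0, 2500, 50))
  expect_equal(surface_flux(fw1), 40 * 0.25)
  # conservation for random zone configurations
  set.seed(31)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    b <- c(0, sort(sample(seq(200, 2300, 100), k - 1)), 2500)
    r <- runif(k, -80, 30)
    fw <- forward_profile(b, r, 250, 0.6, 6e-7, seq(0, 2500, 100))
    expect_equal(surface_flux(fw), -sum(r * diff(b) / 1e4), tolerance = 1e-8)
  }
})

test_that("forward model agrees with a finite-difference oracle", {
  with(o2_scenario, {
    fw <- forward_profile(boundaries, rates, top, porosity, diffusivity,
                          depth_grid_um = seq(0, 2500, 12.5))
    fd <- fd_profile_oracle(boundaries, rates, top, porosity, diffusivity,
                            n_nodes = 2001)
    # compare on the common (10x finer than measurement) grid
    keep <- seq(1, 2001, 10)
    ours <- fw$concentrations[match(round(fd$z_um[keep], 6),
                                    round(fw$depths_um, 6))]
    rel <- abs(ours - fd$conc[keep]) / max(abs(fd$conc))
    expect_lt(max(rel), 1e-3)
  })
})

test_that("forward profiles with opposing zones form an interior maximum", {
  fw <- forward_profile(c(0, 800, 2000), c(60, -35), 150, 0.6, 6e-7,
                        seq(0, 2000, 50))
  i_max <- which.max(fw$concentrations)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(fw$concentrations))
  fd <- fd_profile_oracle(c(0, 800, 2000), c(60, -35), 150, 0.6, 6e-7, 2001)
  keep <- seq(1, 2001, 50)
  ours <- fw$concentrations[match(round(fd$z_um[keep], 6),
                                  round(fw$depths_um, 6))]
  expect_lt(max(abs(ours - fd$conc[keep]) / max(fd$conc)), 1e-3)
})

test_that("surface flux from a raw gradient follows Fick's law", {
  expect_equal(surface_flux(rep(200, 5), depths_um = seq(0, 400, 100)), 0)
  # linear profile with gradient g (umol L-1 per cm)
  g <- -400
  conc <- 250 + g * seq(0, 0.2, 0.05)
  j <- surface_flux(conc, depths_um = seq(0, 2000, 500),
                    porosity = 0.6, diffusivity = 1.2e-9)
  expect_equal(j, -0.6 * 1.2e-9 * 1e4 * g, tolerance = 1e-12)
})

test_that("zone inversion is exact on noiseless forward output", {
  # one zone (rate chosen so the profile stays oxic throughout)
  fw1 <- forward_profile(c(0, 2500), -25, 250, 0.6, 6e-7, seq(0, 2500, 100))
  p1 <- o2_profile(fw1$depths_um, fw1$concentrations, 0.6, 6e-7)
  f1 <- fit_production_zones(p1)
  expect_equal(f1$n_zones, 1)
  expect_equal(f1$zone_rates, -25, tolerance = 1e-6)
  expect_lt(f1$sse, 1e-10)
  # two zones: rates and flux within 0.1%
  with(o2_scenario, {
    fw <- forward_profile(boundaries, rates, top, porosity, diffusivity, grid)
    prof <- o2_profile(grid, fw$concentrations, porosity, diffusivity)
    fit <- fit_production_zones(prof)
    expect_equal(fit$n_zones, 2)
    expect_equal(fit$zone_boundaries_um, boundaries)
    expect_equal(fit$zone_rates, rates, tolerance = 1e-3)
    expect_equal(surface_flux(fit), 10, tolerance = 1e-3)
  })
  # three zones round trip
  b3 <- c(0, 800, 1600, 2500); r3 <- c(-60, -25, -5)
  fw3 <- forward_profile(b3, r3, 250, 0.6, 6e-7, seq(0, 2500, 100))
  p3 <- o2_profile(fw3$depths_um, pmax(fw3$concentrations, 0), 0.6, 6e-7)
  f3 <- fit_production_zones(p3, max_zones = 3)
  expect_equal(f3$n_zones, 3)
  expect_equal(f3$zone_rates, r3, tolerance = 1e-3)
  expect_equal(surface_flux(f3), fw3$surface_flux, tolerance = 1e-3)
})

test_that("best SSE is non-increasing in the candidate zone count", {
  p <- gen_oxygen_profile(o2_scenario$boundaries, o2_scenario$rates,
                          o2_scenario$top, o2_scenario$porosity,
                          o2_scenario$diffusivity, 100, 0.01, seed = 3)
  fit <- fit_production_zones(p, max_zones = 3)
  expect_true(all(diff(fit$sse_by_k) <= 1e-9))
})

test_that("a constant profile yields one zone with zero rate", {
  flat <- o2_profile(seq(0, 2000, 200), rep(180, 11))
  fit <- fit_production_zones(flat)
  expect_equal(fit$n_zones, 1)
  expect_equal(fit$zone_rates, 0, tolerance = 1e-12)
  expect_equal(surface_flux(fit), 0, tolerance = 1e-12)
})

test_that("anoxic boundary interpolates the 1% crossing", {
  ab <- anoxic_boundary(c(250, 100, 2, 0), air_saturation = 250,
                        depths_um = c(0, 500, 1500, 2000))
  expect_true(ab$reached)
  expect_equal(ab$threshold_umol_l, 2.5)
  # independent interpolation: 500 + (2.5-100)/(2-100)*1000
  expect_equal(ab$depth_um, 500 + (2.5 - 100) / (2 - 100) * 1000,
               tolerance = 1e-9)
  expect_equal(ab$depth_um, 1494.9, tolerance = 1e-4)
  # never anoxic
  ab2 <- anoxic_boundary(c(250, 240, 230, 220), air_saturation = 250,
                         depths_um = c(0, 500, 1000, 1500))
  expect_false(ab2$reached)
  expect_true(is.na(ab2$depth_um))
  # crossing exactly at a grid point
  ab3 <- anoxic_boundary(c(250, 2.5, 1, 0), air_saturation = 250,
                         depths_um = c(0, 500, 1000, 1500))
  expect_equal(ab3$depth_um, 500)
  # a dip that recovers does not count: boundary is where O2 stays below
  ab4 <- anoxic_boundary(c(250, 1, 100, 2, 0), air_saturation = 250,
                         depths_um = c(0, 400, 800, 1200, 1600))
  expect_gt(ab4$depth_um, 800)
})

test_that("o2_profile validates its invariants", {
  expect_error(o2_profile(c(0, 100, 50, 200), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(o2_profile(c(0, 100, 200), c(1, 2, 3)), ">= 4")
  expect_error(o2_profile(c(0, 100, 200, 300), c(1, -2, 3, 4)), ">= 0")
  expect_error(o2_profile(c(0, 100, 200, 300), c(1, 2, 3, 4), porosity = 1.5),
               "porosity")
})
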