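test_that("generators are deterministic under a fixed seed", {
  g1 <- gen_gas_timeseries(seed = 42)
  g2 <- gen_gas_timeseries(seed = 42)
  expect_identical(g1, g2)
  i1 <- gen_isotope_series(noise_sd = 0.5, seed = 7)
  i2 <- gen_isotope_series(noise_sd = 0.5, seed = 7)
  expect_identical(i1, i2)
  q1 <- gen_qpcr_plate(qpcr_expression_truth(2), seed = 3)
  q2 <- gen_qpcr_plate(qpcr_expression_truth(2), seed = 3)
  expect_identical(q1, q2)
})

test_that("noiseless gas series are exactly linear and carry their truth", {
  gas <- gen_gas_timeseries(treatments = data.frame(treatment = "FDN",
                                                    rate = 3800),
                            replicates = 1, noise_sd = 0, seed = 1)
  truth <- attr(gas, "truth")
  expect_equal(truth$treatments$rate, 3800)
  r <- fit_rates(gas)
  expect_equal(r$rate, 3800, tolerance = 1e-9)
  expect_equal(r$r_squared, 1)
})

test_that("gas generator emits all four gases with physical metadata", {
  gas <- gen_gas_timeseries(treatments = data.frame(treatment = c("FDN", "FLO"),
                                                    rate = c(100, 10)),
                            replicates = 2, seed = 5)
  expect_setequal(unique(gas$gas), c("CH4", "CO2", "H2", "O2"))
  expect_equal(nrow(gas), 2 * 2 * 4 * 7)
  # oxic headspace holds 21% O2, anoxic none
  expect_true(all(gas$ppmv[gas$gas == "O2" & gas$treatment == "FLO"] == 2.1e5))
  expect_true(all(gas$ppmv[gas$gas == "O2" & gas$treatment == "FDN"] == 0))
  expect_true(all(gas$ppmv >= 0))
})

test_that("isotope generator keeps exact pool mass balance", {
  iso <- gen_isotope_series(rate = 500, f_hydrogenotrophic = 0.4,
                            delta_ma = -20.5, delta_mc = -75, noise_sd = 0)
  truth <- attr(iso, "truth")
  # recompute the amount-weighted pool delta from the per-interval inputs
  days <- iso$day
  amounts <- iso$ch4_nmol_gdw
  for (i in seq_along(days)[-1]) {
    new_amt <- amounts[i] - amounts[i - 1]
    pool <- sum(diff(amounts[1:i]) * truth$delta_new[2:i])
    expect_equal(truth$delta_pool[i], pool / amounts[i], tolerance = 1e-9)
  }
  # pure hydrogenotrophic series sits on the delta_mc end member
  pure <- gen_isotope_series(f_hydrogenotrophic = 1, delta_mc = -75,
                             noise_sd = 0)
  expect_true(all(pure$delta_ch4[-1] == -75))
  p <- partition_pathways(pure$delta_ch4[nrow(pure)], -20.5, -75)
  expect_equal(p$f_acetoclastic, 0)
})

test_that("isotope generator with a fixed alpha ties delta_mc to delta_co2", {
  iso <- gen_isotope_series(f_hydrogenotrophic = 1, alpha = 1.066,
                            delta_co2 = -20, noise_sd = 0)
  d <- iso[!is.na(iso$delta_ch4), ]
  fr <- apparent_fractionation(d$delta_co2, d$delta_ch4)
  expect_equal(unique(round(fr$alpha_app, 9)), 1.066)
})

test_that("oxygen generator records truth and inverts exactly when noiseless", {
  p <- gen_oxygen_profile(c(0, 1200, 2500), c(-50, -15), 250, 0.6, 6e-7,
                          100, noise_fraction = 0, seed = 9)
  truth <- attr(p, "truth")
  fit <- fit_production_zones(p)
  expect_equal(fit$zone_rates, truth$zone_rates, tolerance = 1e-6)
  expect_equal(surface_flux(fit), truth$surface_flux, tolerance = 1e-6)
  # zero-rate zones give a flat profile
  flat <- gen_oxygen_profile(c(0, 1000, 2000), c(0, 0), 250,
                             noise_fraction = 0)
  expect_true(all(flat$concentrations == 250))
})

test_that("qPCR generator follows the standard curve exactly at zero noise", {
  tr <- data.frame(assay = "a", treatment = "T", template = "DNA",
                   replicate = 1:3, copies = c(1e3, 1e5, 1e7))
  plate <- gen_qpcr_plate(tr, curve_slope = -3.5, curve_intercept = 38,
                          ct_noise_sd = 0)
  expect_equal(plate$ct, 38 - 3.5 * log10(tr$copies))
  rec <- copies_from_ct(plate$ct, -3.5, 38)
  expect_equal(rec$copies_in_reaction, tr$copies, tolerance = 1e-9)
})

test_that("expression preset is recovered within 2 SE over triplicates", {
  plate <- gen_qpcr_plate(qpcr_expression_truth(3.21), ct_noise_sd = 0.15,
                          seed = 42)
  e <- expression_table(plate, "katE-gene", "katE-transcript",
                        list(c("FDN", "FDO")))
  expect_lt(abs(e$fold_change - 3.21), 2 * e$standard_error + 1e-12)
})

test_that("simulate_experiment writes a reproducible file bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_experiment(d1, seed = 42)
  p2 <- simulate_experiment(d2, seed = 42)
  for (nm in names(p1)) {
    expect_true(file.exists(p1[[nm]]))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  # ground-truth sidecar is readable and carries the generator presets
  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  expect_equal(truth$qpcr_fold_change, 3.21)
  expect_equal(truth$isotopes_oxic$alpha, 1.066)
})
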