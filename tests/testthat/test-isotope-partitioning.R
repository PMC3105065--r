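test_that("fraction of new methane follows from the amount increase", {
  expect_equal(fraction_new(0, 100), 1)
  expect_equal(fraction_new(100, 400), 0.75)
  expect_error(fraction_new(100, 100), "no net production")
  expect_error(fraction_new(200, 100), "no net production")
  expect_error(fraction_new(-1, 100), ">= 0")
})

test_that("newly formed delta satisfies two-pool mass balance", {
  expect_equal(newly_formed_delta(-60, -50, 0.5), -40)
  expect_equal(newly_formed_delta(-70, -40, 0.75), -30)
  expect_equal(newly_formed_delta(-12, -55, 1), -55) # fn = 1: all methane new
  expect_error(newly_formed_delta(-60, -50, 0), "\\(0, 1]")
  expect_error(newly_formed_delta(-60, -50, 1.2), "\\(0, 1]")
  set.seed(11)
  for (i in 1:50) {
    d1 <- runif(1, -110, 0); d2 <- runif(1, -110, 0); fn <- runif(1, 0.01, 1)
    dn <- newly_formed_delta(d1, d2, fn)
    expect_equal(fn * dn + (1 - fn) * d1, d2, tolerance = 1e-9)
  }
})

test_that("apparent fractionation factor matches its definition", {
  same <- apparent_fractionation(-30, -30)
  expect_equal(same$alpha_app, 1)
  expect_equal(same$epsilon_app, 0)
  # anoxic treatment means: CO2 midpoint -11.5, CH4 -35
  anox <- apparent_fractionation(-11.5, -35)
  expect_equal(anox$alpha_app, 988.5 / 965, tolerance = 1e-12)
  expect_equal(anox$alpha_app, 1.0244, tolerance = 1e-4)
  expect_error(apparent_fractionation(-11.5, -1000), "> -1000")
})

test_that("alpha and epsilon interconvert exactly", {
  expect_equal(alpha_to_epsilon(1), 0)
  expect_equal(alpha_to_epsilon(1.066), 66)
  expect_equal(epsilon_to_alpha(25), 1.025)
  for (a in seq(0.9, 1.2, by = 0.01)) {
    expect_identical(epsilon_to_alpha(alpha_to_epsilon(a)), a)
  }
  expect_error(alpha_to_epsilon(0), "> 0")
})

test_that("pathway partition interpolates between end members and clamps", {
  p <- partition_pathways(-35, -20.5, -75)
  expect_equal(p$f_hydrogenotrophic, 14.5 / 54.5, tolerance = 1e-12)
  expect_equal(p$f_acetoclastic, 0.734, tolerance = 1e-3)
  expect_false(p$clamped)

  # acetate fractionation -25.6 pushes the acetoclastic end member past the
  # measurement: raw fraction negative, clamped to a fully acetoclastic 1.00
  p2 <- partition_pathways(-35, acetate_endmember(-20.5, -25.6), -75)
  expect_true(p2$clamped)
  expect_lt(p2$raw_f_hydrogenotrophic, 0)
  expect_identical(p2$f_acetoclastic, 1)

  p3 <- partition_pathways(-75, -20.5, -75)
  expect_equal(p3$f_hydrogenotrophic, 1)
  expect_equal(p3$f_acetoclastic, 0)
  expect_error(partition_pathways(-35, -50, -50), "degenerate end members")
})

test_that("partition closure and monotonicity hold for random inputs", {
  set.seed(21)
  for (i in 1:50) {
    ems <- sort(runif(2, -120, -10))
    dma <- sample(ems)[1]; dmc <- setdiff(ems, dma)
    d <- runif(1, -130, 0)
    p <- partition_pathways(d, dma, dmc)
    expect_equal(p$f_hydrogenotrophic + p$f_acetoclastic, 1)
    expect_gte(p$f_hydrogenotrophic, 0)
    expect_lte(p$f_hydrogenotrophic, 1)
    # moving delta_ch4 toward delta_mc moves the raw hydrogenotrophic share
    # toward 1, whatever the ordering of the end members
    d2 <- d + 0.1 * (dmc - d)
    p2 <- partition_pathways(d2, dma, dmc)
    expect_lte(abs(1 - p2$raw_f_hydrogenotrophic),
               abs(1 - p$raw_f_hydrogenotrophic) + 1e-12)
  }
})

test_that("acetate end member adds the configured fractionation", {
  expect_equal(acetate_endmember(-20.5, 0), -20.5)
  expect_equal(acetate_endmember(-20.5, -25.6), -46.1)
  expect_equal(acetate_endmember(0, 0), 0)
})

test_that("CO2 source mixing attributes carbonate vs organic carbon", {
  expect_equal(co2_source_fraction(-20.5)$fraction_carbonate, 0)
  expect_equal(co2_source_fraction(-4.09)$fraction_carbonate, 1)
  expect_equal(co2_source_fraction(-11.5)$fraction_carbonate, 9 / 16.41,
               tolerance = 1e-12)
  expect_true(co2_source_fraction(-30)$clamped)
  expect_error(co2_source_fraction(-10, -5, -5), "degenerate")
})

test_that("delta-method uncertainty propagates through the partition", {
  p0 <- partition_with_uncertainty(-35, -20.5, -75)
  expect_equal(p0$standard_error, 0)
  p1 <- partition_with_uncertainty(-35, -20.5, -75, se_ch4 = 2)
  expect_equal(p1$standard_error, 2 / 54.5, tolerance = 1e-12)
  expect_equal(p1$standard_error, 0.0367, tolerance = 1e-3)
  expect_error(partition_with_uncertainty(-35, -20.5, -75, se_ch4 = -1), ">= 0")
})

test_that("partitions recover generator pathway fractions on noiseless data", {
  for (f_true in c(0, 0.27, 0.5, 0.8, 1)) {
    iso <- gen_isotope_series(rate = 1000, f_hydrogenotrophic = f_true,
                              delta_ma = -20.5, delta_mc = -75, noise_sd = 0)
    d_final <- iso$delta_ch4[nrow(iso)]
    p <- partition_pathways(d_final, -20.5, -75)
    expect_equal(p$f_hydrogenotrophic, f_true, tolerance = 0.01)
  }
})

test_that("new-methane series skips intervals without net production", {
  iso <- data.frame(day = c(0, 7, 14, 21),
                    delta_ch4 = c(NA, -70, -60, -60),
                    ch4_nmol_gdw = c(0, 100, 400, 390))
  expect_warning(res <- new_methane_series(iso[-1, ]), "skipped")
  expect_equal(nrow(res), 1)
  expect_equal(res$fraction_new, 0.75)
  # mass balance: 0.25*(-70) + 0.75*delta_new = -60
  expect_equal(0.25 * -70 + 0.75 * res$delta_new, -60, tolerance = 1e-9)
})
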