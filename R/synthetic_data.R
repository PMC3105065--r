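# Synthetic microcosm data with known ground truth. Each generator emits
# the same tabular layout the validated readers expect, plus a `truth`
# attribute recording every generating parameter, so recovery tests can
# compare pipeline output against the construction.
#
# Noise models (modelling choices, kept deliberately simple): multiplicative
# Gaussian on cumulative gas amounts, additive Gaussian (permil) on delta
# values, additive Gaussian (cycles) on Ct values.

#' Default per-treatment methane production rates
#'
#' The eight factorial treatments with the mean CH4 production rates used
#' as generator presets: dark anoxic treatments produce fast (FDN 3800,
#' WDN 1500 nmol gdw-1 d-1), dark oxic slowly (FDO 41.6, WDO 9.2), and the
#' four light treatments at the 21.7 nmol gdw-1 d-1 oxic/oxygenic mean.
#'
#' @return Data frame with `treatment` and `rate` (nmol gdw-1 d-1).
#' @export
treatment_presets <- function() {
  data.frame(
    treatment = c("FDN", "WDN", "FDO", "WDO", "FLN", "FLO", "WLN", "WLO"),
    rate = c(3800, 1500, 41.6, 9.2, 21.7, 21.7, 21.7, 21.7),
    stringsAsFactors = FALSE
  )
}

#' Generate headspace gas accumulation time series
#'
#' Cumulative CH4 per microcosm follows `true_rate * day * (1 + e)` with
#' `e ~ N(0, noise_sd)` independently per sample, floored at zero, then
#' converted to a mixing ratio through the inverse ideal-gas conversion.
#' Companion CO2 (saturating accumulation), O2 (21 percent in oxic, zero in
#' anoxic headspaces) and H2 (trace) series use fixed preset trajectories.
#'
#' @param treatments Data frame with `treatment` and `rate` columns
#'   (nmol gdw-1 d-1). Default [treatment_presets()].
#' @param days Sampling days. Default `seq(0, 42, 7)`.
#' @param replicates Microcosms per treatment. Default 3.
#' @param noise_sd Multiplicative noise SD on amounts. Default 0.1.
#' @param seed Integer seed; set for reproducibility.
#' @param headspace_ml,soil_gdw,temp_k,pressure_pa Physical metadata
#'   written into every row.
#' @param gases Which gases to emit. Default all four.
#' @return Long data frame in the `gas_timeseries.csv` layout
#'   (`microcosm_id`, `treatment`, `gas`, `day`, `ppmv`, `headspace_ml`,
#'   `soil_gdw`, `temp_k`, `pressure_pa`), with a `truth` attribute.
#' @export
gen_gas_timeseries <- function(treatments = treatment_presets(),
                               days = seq(0, 42, 7), replicates = 3,
                               noise_sd = 0.1, seed = NULL,
                               headspace_ml = 100, soil_gdw = 20,
                               temp_k = 298.15, pressure_pa = 101325,
                               gases = c("CH4", "CO2", "H2", "O2")) {
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ppmv_per_nmol <- 1 / mixing_ratio_to_amount(1, headspace_ml, temp_k, pressure_pa)
  rows <- list()
  for (i in seq_len(nrow(treatments))) {
    tr <- treatments$treatment[i]
    rate <- treatments$rate[i]
    oxic <- substr(tr, 3, 3) == "O"
    for (r in seq_len(replicates)) {
      id <- sprintf("%s-%d", tr, r)
      for (gas in gases) {
        nmol_gdw <- switch(
          gas,
          CH4 = pmax(rate * days * (1 + rnorm(length(days), 0, noise_sd)), 0),
          # CO2: fast accumulation saturating within the first week
          CO2 = 2e4 * (1 - exp(-days / 3)) * (1 + rnorm(length(days), 0, noise_sd)),
          # H2: trace levels, higher in the light
          H2 = (if (substr(tr, 2, 2) == "L") 5 else 0.5) *
            pmax(1 + rnorm(length(days), 0, noise_sd), 0),
          # O2 is a headspace state, not an accumulation: constant level
          O2 = NULL
        )
        ppmv <- if (gas == "O2") {
          rep(if (oxic) 2.1e5 else 0, length(days))
        } else {
          nmol_gdw * soil_gdw * ppmv_per_nmol
        }
        rows[[length(rows) + 1]] <- data.frame(
          microcosm_id = id, treatment = tr, gas = gas, day = days,
          ppmv = ppmv, headspace_ml = headspace_ml, soil_gdw = soil_gdw,
          temp_k = temp_k, pressure_pa = pressure_pa,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(treatments = treatments, days = days,
                             replicates = replicates, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate an isotope time series with controlled pathway mixing
#'
#' Methane accumulates linearly at `rate`; in each sampling interval the
#' newly formed methane carries the signature
#' `f_hydrogenotrophic * delta_mc + (1 - f_hydrogenotrophic) * delta_ma`,
#' and the cumulative pool delta is updated by exact isotope mass balance.
#' When `alpha` is supplied, the hydrogenotrophic end member is derived
#' from the CO2 signature as `delta_mc = (delta_co2 + 1000)/alpha - 1000`
#' (a fixed CO2 -> CH4 fractionation). Optional Gaussian noise (permil) is
#' added to the reported deltas only - the underlying mass balance stays
#' exact.
#'
#' @param rate CH4 production rate, nmol gdw-1 d-1.
#' @param days Sampling days (first day is the start, amount 0).
#' @param f_hydrogenotrophic Fraction of new CH4 from H2/CO2, in \[0, 1\].
#' @param delta_ma Acetoclastic end member, permil. Default -20.5.
#' @param delta_mc Hydrogenotrophic end member, permil. Ignored when
#'   `alpha` is given.
#' @param alpha Optional fixed CO2 -> CH4 fractionation factor generating
#'   `delta_mc` from `delta_co2`.
#' @param delta_co2 CO2 signature trajectory, permil: scalar or one value
#'   per sampling day.
#' @param noise_sd Additive Gaussian noise on reported deltas, permil.
#' @param replicates Number of replicate series. Default 1.
#' @param treatment Treatment code label. Default `"FDN"`.
#' @param seed Integer seed.
#' @return Data frame in the `isotopes.csv` layout (`microcosm_id`,
#'   `treatment`, `day`, `delta_ch4`, `delta_co2`, `ch4_nmol_gdw`; day-0
#'   rows carry `NA` deltas since no methane exists yet), with a `truth`
#'   attribute holding the noiseless pools.
#' @export
gen_isotope_series <- function(rate = 3800, days = seq(0, 42, 7),
                               f_hydrogenotrophic = 0.27,
                               delta_ma = -20.5, delta_mc = -75,
                               alpha = NULL, delta_co2 = -11.5,
                               noise_sd = 0, replicates = 1,
                               treatment = "FDN", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (f_hydrogenotrophic < 0 || f_hydrogenotrophic > 1) {
    stop("f_hydrogenotrophic must lie in [0, 1]")
  }
  dco2 <- rep_len(delta_co2, length(days))
  dmc <- if (!is.null(alpha)) (dco2 + 1000) / alpha - 1000 else rep_len(delta_mc, length(days))
  delta_new <- f_hydrogenotrophic * dmc + (1 - f_hydrogenotrophic) * delta_ma

  amounts <- rate * days
  # exact cumulative mass balance of the noiseless pool
  delta_pool <- rep(NA_real_, length(days))
  for (i in seq_along(days)[-1]) {
    d_amt <- amounts[i] - amounts[i - 1]
    delta_pool[i] <- if (amounts[i - 1] == 0) {
      delta_new[i]
    } else {
      (amounts[i - 1] * delta_pool[i - 1] + d_amt * delta_new[i]) / amounts[i]
    }
  }

  rows <- lapply(seq_len(replicates), function(r) {
    data.frame(
      microcosm_id = sprintf("%s-%d", treatment, r), treatment = treatment,
      day = days,
      delta_ch4 = delta_pool + rnorm(length(days), 0, noise_sd),
      delta_co2 = ifelse(is.na(delta_pool), NA_real_,
                         dco2 + rnorm(length(days), 0, noise_sd)),
      ch4_nmol_gdw = amounts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    rate = rate, f_hydrogenotrophic = f_hydrogenotrophic, delta_ma = delta_ma,
    delta_mc = dmc, alpha = alpha, delta_new = delta_new,
    delta_pool = delta_pool, delta_co2 = dco2, noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a noisy steady-state oxygen microprofile
#'
#' Forward-models the profile from true zones via [forward_profile()] and
#' adds Gaussian measurement noise proportional to the top concentration.
#'
#' @param zone_boundaries_um,zone_rates,top_concentration,porosity,diffusivity
#'   Passed to [forward_profile()].
#' @param depth_step_um Measurement grid spacing, um. Default 100.
#' @param noise_fraction Noise SD as a fraction of `top_concentration`.
#'   Default 0.01.
#' @param seed Integer seed.
#' @return An [o2_profile()] object with a `truth` attribute (true zones,
#'   rates, surface flux and the noiseless concentrations).
#' @export
gen_oxygen_profile <- function(zone_boundaries_um, zone_rates,
                               top_concentration = 250, porosity = 0.6,
                               diffusivity = 1.2e-9, depth_step_um = 100,
                               noise_fraction = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(zone_boundaries_um[1], zone_boundaries_um[length(zone_boundaries_um)],
              by = depth_step_um)
  fw <- forward_profile(zone_boundaries_um, zone_rates, top_concentration,
                        porosity, diffusivity, grid)
  conc <- fw$concentrations + rnorm(length(grid), 0,
                                    noise_fraction * top_concentration)
  prof <- o2_profile(grid, pmax(conc, 0), porosity, diffusivity)
  attr(prof, "truth") <- list(
    zone_boundaries_um = zone_boundaries_um, zone_rates = zone_rates,
    surface_flux = fw$surface_flux, concentrations = fw$concentrations,
    noise_fraction = noise_fraction, seed = seed)
  prof
}

#' Generate a qPCR plate from true copy numbers
#'
#' Ct values follow the standard curve
#' `Ct = intercept + slope * log10(copies) + N(0, ct_noise_sd)`.
#'
#' @param truth Data frame with columns `assay`, `treatment`, `template`
#'   (`"DNA"`/`"cDNA"`), `replicate`, `copies` (true copies in reaction).
#' @param curve_slope,curve_intercept Standard-curve parameters. Defaults
#'   -3.3219 (100 percent efficiency) and 37.
#' @param ct_noise_sd Gaussian Ct noise, cycles. Default 0.15.
#' @param seed Integer seed.
#' @return Data frame in the `qpcr.csv` layout (`assay`, `sample_id`,
#'   `treatment`, `template`, `replicate`, `ct`, `curve_slope`,
#'   `curve_intercept`, `dilution`, `gdw`), with a `truth` attribute.
#' @export
gen_qpcr_plate <- function(truth, curve_slope = -3.3219, curve_intercept = 37,
                           ct_noise_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("assay", "treatment", "template", "replicate", "copies")
  miss <- setdiff(need, names(truth))
  if (length(miss) > 0) stop("truth is missing column(s): ", paste(miss, collapse = ", "))
  if (any(truth$copies <= 0)) stop("true copies must be > 0")
  ct <- curve_intercept + curve_slope * log10(truth$copies) +
    rnorm(nrow(truth), 0, ct_noise_sd)
  out <- data.frame(
    assay = truth$assay,
    sample_id = sprintf("%s-%d", truth$treatment, truth$replicate),
    treatment = truth$treatment, template = truth$template,
    replicate = truth$replicate, ct = ct,
    curve_slope = curve_slope, curve_intercept = curve_intercept,
    dilution = 1, gdw = 1, stringsAsFactors = FALSE)
  attr(out, "truth") <- c(as.list(truth), list(
    curve_slope = curve_slope, curve_intercept = curve_intercept,
    ct_noise_sd = ct_noise_sd, seed = seed))
  out
}

#' True copy numbers realizing a target expression fold change
#'
#' Builds a `truth` table for [gen_qpcr_plate()] in which the transcript to
#' gene ratio of the second treatment is `fold_change` times that of the
#' first, so the 2^-ddCt estimator (with a perfect-efficiency curve) has
#' the given true value.
#'
#' @param fold_change True relative-expression fold change (second vs
#'   first treatment).
#' @param treatments Character length-2, the matched pair. Default
#'   `c("FDN", "FDO")`.
#' @param gene_assay,transcript_assay Assay labels.
#' @param n_replicates Replicates per treatment. Default 3.
#' @param gene_copies True gene copies per reaction. Default 1e6.
#' @param base_expression Transcript/gene ratio in the first treatment.
#'   Default 0.1.
#' @return Truth data frame for [gen_qpcr_plate()].
#' @export
qpcr_expression_truth <- function(fold_change, treatments = c("FDN", "FDO"),
                                  gene_assay = "katE-gene",
                                  transcript_assay = "katE-transcript",
                                  n_replicates = 3, gene_copies = 1e6,
                                  base_expression = 0.1) {
  if (fold_change <= 0) stop("fold_change must be > 0")
  rows <- list()
  for (i in seq_along(treatments)) {
    expr <- base_expression * if (i == 2) fold_change else 1
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        assay = c(gene_assay, transcript_assay), treatment = treatments[i],
        template = c("DNA", "cDNA"), replicate = r,
        copies = c(gene_copies, gene_copies * expr), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fold_change") <- fold_change
  out
}

#' Simulate a complete microcosm experiment to disk
#'
#' Writes the four pipeline input CSVs (gas, isotopes, O2 profiles, qPCR)
#' plus a `truth.json` sidecar into a directory, all generated from the
#' treatment presets under one seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed. Default 42.
#' @param noise_sd Gas/delta noise level. Default 0.1 (gas) and 0.5 permil
#'   scaled internally for deltas.
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_experiment <- function(out_dir, seed = 42, noise_sd = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  gas <- gen_gas_timeseries(noise_sd = noise_sd, seed = seed)
  iso_anox <- gen_isotope_series(rate = 3800, f_hydrogenotrophic = 0.27,
                                 delta_co2 = -11.5, noise_sd = 0.5,
                                 replicates = 3, treatment = "FDN",
                                 seed = seed + 1)
  iso_oxic <- gen_isotope_series(rate = 21.7, f_hydrogenotrophic = 1,
                                 alpha = 1.066, delta_co2 = -20, noise_sd = 0.5,
                                 replicates = 3, treatment = "FLO",
                                 seed = seed + 2)
  iso <- rbind(iso_anox, iso_oxic)
  profs <- lapply(1:3, function(r) {
    p <- gen_oxygen_profile(c(0, 1000, 2500), c(-70, -20),
                            top_concentration = 250, diffusivity = 6e-7,
                            seed = seed + 10 + r)
    data.frame(microcosm_id = sprintf("FLO-%d", r), treatment = "FLO",
               depth_um = p$depths_um, conc_umol_l = p$concentrations)
  })
  o2 <- do.call(rbind, profs)
  qtruth <- qpcr_expression_truth(3.21)
  qpcr <- gen_qpcr_plate(qtruth, seed = seed + 20)

  paths <- list(
    gas = file.path(out_dir, "gas_timeseries.csv"),
    isotopes = file.path(out_dir, "isotopes.csv"),
    o2 = file.path(out_dir, "o2_profiles.csv"),
    qpcr = file.path(out_dir, "qpcr.csv"),
    truth = file.path(out_dir, "truth.json"))
  write.csv(gas, paths$gas, row.names = FALSE)
  write.csv(iso, paths$isotopes, row.names = FALSE)
  write.csv(o2, paths$o2, row.names = FALSE)
  write.csv(qpcr, paths$qpcr, row.names = FALSE)
  truth <- list(seed = seed, gas = attr(gas, "truth"),
                isotopes_anoxic = attr(iso_anox, "truth"),
                isotopes_oxic = attr(iso_oxic, "truth"),
                qpcr_fold_change = attr(qtruth, "fold_change"))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
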