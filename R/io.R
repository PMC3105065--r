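# Validated tabular readers and end-to-end pipeline orchestration.
# All inputs are plain UTF-8 comma-separated files with '.' decimals; every
# schema error names the offending column and row.

.read_validated <- function(path, required, numeric_cols = character(),
                            key_cols = NULL, defaults = list()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(required, names(defaults)), names(tab))
  if (length(miss) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  for (col in names(defaults)) {
    if (!col %in% names(tab)) {
      tab[[col]] <- defaults[[col]]
      message("column '", col, "' absent in ", basename(path),
              "; default ", defaults[[col]], " applied")
    } else if (anyNA(tab[[col]])) {
      n_na <- sum(is.na(tab[[col]]))
      tab[[col]][is.na(tab[[col]])] <- defaults[[col]]
      message(n_na, " missing '", col, "' cell(s) in ", basename(path),
              "; default ", defaults[[col]], " applied")
    }
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")
    if (length(bad) > 0) {
      stop("unparsable numeric cell(s) in column '", col, "' of ",
           basename(path), " at row(s): ", paste(bad, collapse = ", "))
    }
    tab[[col]] <- v
  }
  if (!is.null(key_cols)) {
    key <- do.call(paste, c(tab[key_cols], sep = "\r"))
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      stop("duplicate (", paste(key_cols, collapse = ", "), ") key in ",
           basename(path), " at rows: ", paste(which(dup), collapse = ", "))
    }
  }
  tab$.row <- seq_len(nrow(tab))
  tab
}

#' Read a headspace gas time-series table
#'
#' Expected header: `microcosm_id,treatment,gas,day,ppmv,headspace_ml,
#' soil_gdw,temp_k,pressure_pa`. Missing `temp_k`/`pressure_pa` cells (or
#' columns) receive the incubation defaults 298.15 K and 101325 Pa, with a
#' message. Duplicate `(microcosm_id, day, gas)` keys are schema errors.
#'
#' @param path CSV path.
#' @return Validated data frame (row numbers in `.row`).
#' @export
read_gas_table <- function(path) {
  .read_validated(
    path,
    required = c("microcosm_id", "treatment", "gas", "day", "ppmv",
                 "headspace_ml", "soil_gdw", "temp_k", "pressure_pa"),
    numeric_cols = c("day", "ppmv", "headspace_ml", "soil_gdw",
                     "temp_k", "pressure_pa"),
    key_cols = c("microcosm_id", "day", "gas"),
    defaults = list(temp_k = 298.15, pressure_pa = 101325))
}

#' Read an isotope time-series table
#'
#' Expected header: `microcosm_id,treatment,day,delta_ch4,delta_co2,
#' ch4_nmol_gdw`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_isotope_table <- function(path) {
  .read_validated(
    path,
    required = c("microcosm_id", "treatment", "day", "delta_ch4",
                 "delta_co2", "ch4_nmol_gdw"),
    numeric_cols = c("day", "delta_ch4", "delta_co2", "ch4_nmol_gdw"),
    key_cols = c("microcosm_id", "day"))
}

#' Read an oxygen microprofile table
#'
#' Expected header: `microcosm_id,treatment,depth_um,conc_umol_l`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_o2_table <- function(path) {
  .read_validated(
    path,
    required = c("microcosm_id", "treatment", "depth_um", "conc_umol_l"),
    numeric_cols = c("depth_um", "conc_umol_l"),
    key_cols = c("microcosm_id", "depth_um"))
}

#' Read a qPCR plate table
#'
#' Expected header: `assay,sample_id,treatment,template,replicate,ct,
#' curve_slope,curve_intercept,dilution,gdw`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_qpcr_table <- function(path) {
  .read_validated(
    path,
    required = c("assay", "sample_id", "treatment", "template", "replicate",
                 "ct", "curve_slope", "curve_intercept", "dilution", "gdw"),
    numeric_cols = c("replicate", "ct", "curve_slope", "curve_intercept",
                     "dilution", "gdw"),
    key_cols = c("assay", "sample_id", "template", "replicate"))
}

#' Run the full analysis pipeline
#'
#' Chains all stages over the four input tables: production-rate regression
#' and treatment summaries; apparent fractionation and pathway partitions
#' per acetate-fractionation scenario; oxygen-profile inversion with surface
#' fluxes and anoxic boundaries; qPCR relative expression for configured
#' treatment pairs; three-factorial ANOVA of log-transformed CH4 rates; and
#' the areal/global upscaling grid. Per-stage TSV/JSON files plus a single
#' `summary.json` are written to `out_dir`. Repeated runs on identical
#' inputs produce identical outputs.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `inputs` (paths `gas`, `isotopes`, `o2`, `qpcr`; any may be NULL to
#'   skip the stage), `window` (regression window, default `c(0, 42)`),
#'   `end_members` (`delta_organic`, `delta_carbonate`, `delta_mc`),
#'   `scenarios` (acetate-to-methane fractionations, default `c(0, -25.6)`),
#'   `o2` (`porosity`, `diffusivity`, `max_zones`, `alpha`,
#'   `air_saturation`), `qpcr_pairs` (list of `c(first, second)` treatment
#'   codes), `qpcr_assays` (`gene`, `transcript`), `upscale` (`wet_weeks`,
#'   `crust_areal_density`, `desert_area_km2`, `treatments` used for the
#'   rate).
#' @param out_dir Output directory.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- function(name, default) {
    v <- config[[name]]
    if (is.null(v)) default else v
  }
  summary <- list()

  # -- gas kinetics ---------------------------------------------------------
  if (!is.null(config$inputs$gas)) {
    gas <- read_gas_table(config$inputs$gas)
    window <- cfg("window", c(0, 42))
    rates <- fit_rates(gas, window = window)
    by_tr <- summarize_rates(rates)
    write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(by_tr, file.path(out_dir, "treatment_rates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    summary$rates_nmol_gdw_d <- by_tr
    message("gas_kinetics: ", nrow(gas), " rows -> ", nrow(rates), " rate estimates")

    # factorial ANOVA of log rates (needs all 8 cells)
    rt <- cbind(rates, treatment_code(rates$treatment)[c("wetting", "light", "headspace")])
    ok <- tryCatch({
      rt$log_rate <- log_transform(rt$rate)
      av <- factorial_anova(rt, "log_rate")
      write.table(av, file.path(out_dir, "anova_log_rates.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      summary$anova_log_ch4_rate <- av
      TRUE
    }, error = function(e) {
      message("factorial_stats: skipped (", conditionMessage(e), ")")
      FALSE
    })

    # upscaling from the oxic/oxygenic treatment mean
    up <- cfg("upscale", list())
    oxy <- if (!is.null(up$treatments)) up$treatments else
      by_tr$treatment[substr(by_tr$treatment, 2, 3) %in% c("LN", "LO", "DO")]
    oxy_rates <- by_tr$mean_rate[by_tr$treatment %in% oxy]
    if (length(oxy_rates) > 0) {
      grid <- upscale_grid(
        mean(oxy_rates),
        wet_weeks = if (!is.null(up$wet_weeks)) up$wet_weeks else c(2, 7),
        crust_areal_density = if (!is.null(up$crust_areal_density)) up$crust_areal_density else 5300,
        desert_area_km2 = if (!is.null(up$desert_area_km2)) up$desert_area_km2 else 44e6)
      summary$upscale <- grid
      jsonlite::write_json(grid, file.path(out_dir, "upscale.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }

  # -- isotopes -------------------------------------------------------------
  if (!is.null(config$inputs$isotopes)) {
    iso <- read_isotope_table(config$inputs$isotopes)
    em <- cfg("end_members",
              list(delta_organic = -20.5, delta_carbonate = -4.09, delta_mc = -75))
    scen <- cfg("scenarios", c(0, -25.6))
    per_tr <- lapply(split(iso, iso$treatment), function(d) {
      d <- d[!is.na(d$delta_ch4) & !is.na(d$delta_co2), , drop = FALSE]
      fr <- apparent_fractionation(d$delta_co2, d$delta_ch4)
      mean_d_ch4 <- mean(d$delta_ch4)
      parts <- lapply(scen, function(s) {
        p <- partition_pathways(mean_d_ch4,
                                acetate_endmember(em$delta_organic, s),
                                em$delta_mc)
        list(acetate_fractionation_permil = s,
             f_hydrogenotrophic = p$f_hydrogenotrophic,
             f_acetoclastic = p$f_acetoclastic, clamped = p$clamped)
      })
      list(n_points = nrow(d), mean_delta_ch4_permil = mean_d_ch4,
           mean_delta_co2_permil = mean(d$delta_co2),
           alpha_app = mean(fr$alpha_app), epsilon_app = mean(fr$epsilon_app),
           partitions = parts)
    })
    summary$isotopes <- per_tr
    jsonlite::write_json(per_tr, file.path(out_dir, "isotopes.json"),
                         auto_unbox = TRUE, digits = NA)
    message("isotope_partitioning: ", length(per_tr), " treatment(s)")
  }

  # -- oxygen profiles ------------------------------------------------------
  if (!is.null(config$inputs$o2)) {
    o2 <- read_o2_table(config$inputs$o2)
    oc <- cfg("o2", list())
    por <- if (!is.null(oc$porosity)) oc$porosity else 0.6
    dif <- if (!is.null(oc$diffusivity)) oc$diffusivity else 1.2e-9
    mz <- if (!is.null(oc$max_zones)) oc$max_zones else 3
    al <- if (!is.null(oc$alpha)) oc$alpha else 0.05
    airsat <- if (!is.null(oc$air_saturation)) oc$air_saturation else 250
    fits <- lapply(split(o2, o2$microcosm_id), function(d) {
      d <- d[order(d$depth_um), ]
      prof <- o2_profile(d$depth_um, d$conc_umol_l, por, dif)
      fit <- fit_production_zones(prof, max_zones = mz, alpha = al)
      ab <- anoxic_boundary(prof, air_saturation = airsat)
      list(treatment = d$treatment[1], n_zones = fit$n_zones,
           zone_boundaries_um = fit$zone_boundaries_um,
           zone_rates_nmol_cm3_s = fit$zone_rates,
           surface_flux_nmol_cm2_s = fit$surface_flux, sse = fit$sse,
           anoxic_boundary_um = ab$depth_um, anoxic_reached = ab$reached)
    })
    summary$o2_profiles <- fits
    jsonlite::write_json(fits, file.path(out_dir, "o2_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    message("oxygen_profiles: ", length(fits), " profile(s) inverted")
  }

  # -- qPCR -----------------------------------------------------------------
  if (!is.null(config$inputs$qpcr)) {
    plate <- read_qpcr_table(config$inputs$qpcr)
    qa <- cfg("qpcr_assays", list(gene = "katE-gene", transcript = "katE-transcript"))
    pairs <- cfg("qpcr_pairs", list(c("FDN", "FDO")))
    if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
    if (is.character(pairs) && length(pairs) == 2) pairs <- list(pairs)
    expr <- expression_table(plate, qa$gene, qa$transcript, pairs)
    write.table(expr, file.path(out_dir, "relative_expression.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    summary$relative_expression <- expr
    message("qpcr_quant: ", nrow(expr), " treatment pair(s)")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(summary)
}
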