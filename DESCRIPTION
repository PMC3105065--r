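Package: crustgas
Title: Methanogenesis in Biological Soil Crust Microcosms: Gas Kinetics,
    Isotope Pathway Partitioning, Oxygen Microprofiles and qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for factorial biological-soil-crust (BSC)
    microcosm incubations that probe methanogenesis under oxic and anoxic
    conditions. Converts headspace gas mixing ratios to amounts and estimates
    production rates by linear regression; implements the stable carbon
    isotope calculus for methanogenic pathway partitioning (newly formed
    CH4 signature, apparent fractionation factor alpha/epsilon, two
    end-member acetoclastic vs hydrogenotrophic mixing, CO2 carbonate/organic
    source attribution); forward-models and inverts steady-state oxygen
    microprofiles with piecewise-constant production zones to obtain surface
    fluxes and the anoxic boundary depth; quantifies gene and transcript
    copies from qPCR standard curves and relative expression by 2^-ddCt;
    provides balanced three-factorial ANOVA, Welch t-tests and Pearson
    correlations; upscales per-gram rates to areal and global desert methane
    source estimates; and generates synthetic microcosm datasets with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
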