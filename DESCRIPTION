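Package: nitriflux
Title: Isotope-Tracer Nitrification Rates, Seawater Carbonate Chemistry and
    N2O Source Partitioning for Acidification Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how aquatic acidification affects
    nitrification and nitrification-derived nitrous oxide in estuarine and
    coastal waters. Implements 15N-tracer rate estimators for nitrification
    and N2O production from mass-45/46 isotopologue accumulation (including
    an atom-balance diagnostic estimator), a seawater carbonate-system
    solver (pH, DIC, total alkalinity, pCO2) with the Mehrbach constants as
    refit by Dickson and Millero, N2O isotopomer site-preference source
    partitioning with Monte-Carlo uncertainty, acidification dose-response
    curve fitting (polynomials through the origin), global emission
    upscaling arithmetic, and a seeded forward simulator of incubation
    experiments with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
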