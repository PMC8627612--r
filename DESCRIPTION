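Package: srconcord
Title: Concordance of AMSTAR-2 and ROBIS Systematic-Review Appraisals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing quality-of-conduct appraisals of systematic
    reviews made with the AMSTAR-2 and ROBIS instruments. Encodes both
    instruments as validated schemas, implements the AMSTAR-2 overall
    confidence rating, harmonizes item-level responses across eleven matched
    comparisons spanning four methodological domains, and quantifies
    inter-instrument agreement with Gwet's chance-corrected coefficients
    (unweighted AC1 and quadratic-weighted AC2) with delete-one jackknife
    confidence intervals and qualitative agreement bands. A synthetic-cohort
    generator with a latent-quality model supports calibration and testing
    when raw paired assessments are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
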