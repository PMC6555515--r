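Package: fpqual
Title: Summary Indices of Family Planning Quality of Care from Facility Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs facility-level summary measures of family planning
    quality of care from linked facility, provider, and client survey records
    of the Service Provision Assessment (SPA) type. Builds a 53-indicator,
    8-domain binary indicator matrix using mean-dichotomization, exit-interview
    concordance, method-mix and quality-assurance composite rules; computes
    three summary indices (simple additive, domain-weighted additive, and a
    first-principal-component score) with PCA dimensionality diagnostics;
    classifies facilities into weighted terciles; and quantifies inter-method
    agreement with percent agreement and Cohen's kappa with Landis-Koch
    descriptive bands. A hierarchical synthetic-data generator with a known
    latent quality structure makes the full pipeline runnable and testable
    without restricted-access survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
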