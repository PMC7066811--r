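Package: clinexpo
Title: Spatiotemporal Integration of Clinical and Environmental Exposure Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable, plugin-based workflow that joins patient-level
    clinical records (FHIR resources) with environmental exposure surfaces --
    gridded pollutant estimates, road networks, and census socio-environmental
    tables -- by residence geocode and time stamp.  Clinical features are
    extracted per patient per year, exposures are aggregated from hourly,
    daily, or annual series, spatial joins attach nearest-road and census
    attributes, and the merged table is quantile-binned and de-identified
    (HIPAA Safe-Harbor style) into an integrated feature table supporting
    cohort selection and 2x2 chi-square association queries.  Deterministic
    synthetic generators for every input family allow the full pipeline to run
    and be validated with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    yaml,
    jsonlite,
    geosphere,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
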