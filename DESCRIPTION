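Package: yieldclim
Title: Attribution of Crop Yield Variability to Climate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how much of the inter-annual variability in
    detrended crop yields is explained by detrended temperature and
    precipitation variability at the level of political units. Implements a
    candidate set of 27 ordinary-least-squares regression designs built from
    eight climate predictor forms (growing-season and annual temperature and
    precipitation, linear and squared, plus interactions), per-unit selection
    by the Akaike Information Criterion, a nested F-test of the winner against
    an intercept-only null, classification of the selected design into seven
    climate-driver categories, temperature-only and precipitation-only
    reduced-model variance decomposition, harvested-area-weighted aggregation,
    and a leave-group-out bootstrap bias assessment. Includes a synthetic
    panel and gridded-climate generator with known ground truth so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
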