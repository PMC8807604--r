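Package: csarlui
Title: Intensity-Explicit Countryside Species-Area Modelling of Land-Use
    Driven Species Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating native species loss from gridded land-use
    data with a countryside species-area relationship (cSAR) in which the
    habitat contribution of each land-use type is weighted by species
    affinity and by a continuous land-use-intensity index. The package
    builds area-of-habitat-refined species pools from range, habitat and
    elevation data, constructs and scales land-use-intensity surfaces for
    a HANPP-based indicator set and an input/output indicator set,
    decomposes predicted per-cell losses into land-conversion and
    intensity components, converts cell-level loss counts into per-species
    area-of-habitat loss with resampling confidence intervals, and ships a
    synthetic-landscape generator so the whole pipeline can be exercised
    and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
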