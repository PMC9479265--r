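Package: alcospace
Title: Alcohol Outlet Exposure in Children's GPS Activity Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying children's exposure to licensed alcohol
    outlets within GPS-derived activity spaces. Provides nearest-outlet
    linkage of GPS fixes to outlet point locations on a planar metric grid,
    per-fix exposure classification at a configurable distance threshold,
    decomposition of exposure into home and school settings by distance
    band, design-weighted descriptive statistics and quasibinomial
    generalised linear models with Taylor-linearized (stratified,
    clustered) variance estimation, and a calibrated synthetic
    cohort/trajectory simulator with known ground-truth exposure gradients
    across area-deprivation quintiles for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    withr,
    xml2,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
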