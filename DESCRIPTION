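Package: sugarsteps
Title: Added and Free Sugars Estimation for Food Composition Databases and Dietary Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a ten-step decision procedure for estimating added and
    free sugars content (g/100 g) in food composition database items, including
    recursive, yield-adjusted recipe resolution for composite foods over the
    ingredient DAG. Downstream, it converts two-day dietary recall records into
    per-participant daily intakes, adjusts them to habitual (usual) intakes via
    a transform / variance-decomposition / shrinkage model in the style of the
    Multiple Source Method, and reports stratified energy-percent summaries
    against the 10%/5% guideline thresholds. A synthetic-data module generates
    food databases with planted ground-truth sugar sources and two-day surveys
    with known variance components, so the whole pipeline is testable without
    survey microdata.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
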