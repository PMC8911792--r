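Package: marcex
Title: Chemometric Optimization of Bioactive-Compound Extraction from Grape Marc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing factorial solid-liquid extraction experiments
    on grape marc (winemaking pomace). Models extraction yield of total
    polyphenols, flavonoids, tannins and anthocyanins as a parametric
    piecewise cubic-spline curve through the experimental grid
    (temperature x ethanol concentration), identifies optimal extraction
    conditions and fold-changes, quantifies factor-response and
    response-response interdependence with plug-in Shannon entropy and
    mutual information in bits, derives CIELab chroma and hue angle, and
    generates synthetic factorial datasets with tunable surface shape,
    noise and cross-response coupling for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
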