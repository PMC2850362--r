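Package: outgrowr
Title: Survival and Growth Rate from Yeast Outgrowth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies population survival and growth rate of budding
    yeast from multi-well outgrowth optical-density time series, as
    produced by a Bioscreen C plate reader (or any plate reader exporting
    time-by-well tables). Converts the rightward time shift of an
    outgrowth curve, relative to a reference age-point, into a survival
    fraction via the culture's doubling time; builds survival curves and
    survival integrals per well lineage; groups replicate wells and
    compares groups to an experiment-matched reference with percent
    change, log2 ratios and Welch t-tests. Includes a synthetic outgrowth
    simulator with known ground-truth viabilities so the full pipeline
    can be exercised without plate-reader data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    jsonlite
Config/testthat/edition: 3
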