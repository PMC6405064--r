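Package: calciscan
Title: Micro-CT Densitometry and Individual-Level Isotope Statistics for
    Calcareous Microfossil Shells
Version: 0.1.0
Authors@R:
    person("calciscan", "developers", email = "calciscan@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of micro-focus X-ray computed tomography
    (MXCT) scans of calcareous microfossil shells such as planktic
    foraminifers. Implements calcite CT number (CCN) densitometry normalized
    against a standard-calcite reference scanned alongside each specimen,
    Hildebrand-style 3D local wall-thickness estimation, paired
    pre/post-treatment comparison statistics, and group- and
    genotype-stratified stable-isotope (d13C/d18O) analyses with a
    normality-gated parametric/nonparametric branch. Ships a synthetic-data
    module: trochospiral shell phantoms with ground-truth density and
    thickness, polychromatic scan simulation with beam hardening and
    scan-to-scan drift, and parallel-beam filtered back projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
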