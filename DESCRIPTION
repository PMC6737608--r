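Package: paftools
Title: Population Attributable Fractions from Case-Control Data, with
    Fan Plots and Attributable-Fraction Nomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates exact and approximate population attributable
    fractions (PAF) and impact fractions from case-control data for
    binary, multi-category and continuous exposures.  The approximate
    PAF is the control-side exposure prevalence multiplied by an
    averaged log-odds ratio; the package quantifies the bias of that
    approximation over a (prevalence, odds ratio) grid and draws two
    graphical devices that display prevalence, odds ratio and
    approximate PAF simultaneously: a fan plot and a three-axis
    attributable-fraction nomogram with impact-fraction tilting.  Also
    includes stratified bootstrap confidence intervals, a synthetic
    case-control generator with known counterfactual outcomes, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
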