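Package: t1dscan
Title: Life-Stage Exposure Windows and Spatial Scan Statistics for Disease Incidence Mapping
Version: 0.1.0
Authors@R:
    person("Registry", "Geospatial", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for geospatial analysis of disease incidence from
    longitudinal residential histories: assignment of life-stage exposure
    windows (at diagnosis, first five years after birth, five years prior to
    diagnosis, birth to diagnosis), areal incidence mapping with
    observed-versus-expected comparison and quintile display classes, a
    from-scratch discrete-Poisson circular spatial scan statistic with Monte
    Carlo inference for high- and low-risk cluster detection, land-use/land-
    cover profiling of detected clusters, and Dorling cartogram layout.
    Includes a synthetic-data generator that emulates an incidence registry
    (baseline rate, residential mobility, urban population concentration,
    plantable risk clusters) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
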