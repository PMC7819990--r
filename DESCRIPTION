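Package: edgesite
Title: Signal-Quality Comparison of Edge and Center Sites on Planar Silicon Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to compare the extracellular signal quality recorded at
    different site positions on single-shank planar silicon probes. Provides
    built-in geometries for five common probe designs, grouping of recording
    sites into edge and center (or per-column and longitudinal) groups,
    band-pass preprocessing of the spike band, amplitude-distribution analysis
    with a binomial cumulative threshold scan, an in vivo noise-floor estimator
    based on the silent down-states of slow-wave activity, post-sorting single
    unit quality metrics (peak-to-peak amplitude, refractory violations,
    isolation distance), nonparametric group statistics with rank-based effect
    sizes, and a synthetic-recording generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
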