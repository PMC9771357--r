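Package: pcmli
Title: Cerebellar Purkinje-Cell Feedback to Molecular Layer Interneurons: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spiking-network simulation of cerebellar eyelid conditioning with a
    toggleable Purkinje-cell to molecular-layer-interneuron (PC-MLI) feedback
    projection, together with the analysis procedures used to study that circuit:
    eyelid-trace conditioned-response measures, causal-kernel firing-rate
    estimation, trial-wise neural-behavioral correlations with two-Gaussian
    mixture classification, spike/pause/burst-triggered cross-correlograms with
    shuffle nulls, lead-lag (dPC-dMLI) statistics, IPSC short-term-depression and
    readily-releasable-pool estimation, optogenetic map analysis, and seeded
    synthetic-data generators for every input the analysis stack consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    mclust,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
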