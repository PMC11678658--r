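Package: mpsmarkers
Title: Shared and Neuronopathy-Specific Expression Markers in Mucopolysaccharidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative transcriptomic marker analysis for the eleven
    mucopolysaccharidosis (MPS) types/subtypes profiled against a common
    fibroblast control. From a transcript-by-sample FPKM matrix the package
    calls per-disease-group differential expression (one-way ANOVA on
    log2(1 + x) values, Student's post hoc t-tests versus control with
    Bonferroni correction, Benjamini-Hochberg false discovery rates), builds
    cross-type alteration sharing spectra, selects fold-change-filtered
    markers shared across most MPS types, and classifies markers specific to
    the neuronopathic types/subtypes. A synthetic FPKM generator with planted
    marker classes supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
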