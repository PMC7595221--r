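Package: proteonet
Title: Longitudinal Proteome Dysregulation and Interaction-Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for longitudinal label-free
    proteomics of a neurodegeneration model: Hi3 peptide-to-protein rollup,
    minimum-value imputation, quantile normalisation and standardisation;
    consensus time-course differential abundance from a pluggable trio of
    detectors (moderated F, negative-binomial likelihood ratio, polynomial
    likelihood ratio) combined by vote at a Benjamini-Hochberg FDR; Gaussian
    mixture profile clustering with a cluster-count BIC; permutation tests
    for the interaction-network properties (degree, shortest path, largest
    connected component, betweenness) of an altered-protein set;
    hub/bottleneck classification; MCODE dense-module detection; and
    Fisher/minimum-hypergeometric overrepresentation analysis. A synthetic
    data generator reproduces the statistical structure of the study design
    so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    MASS,
    stats,
    utils,
    limma,
    fgsea,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
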