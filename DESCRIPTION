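Package: morbidmap
Title: Mapping Multimorbidity Progression from Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map how multimorbidity progresses in a longitudinal
    cohort. Estimates the directional causal effect of each disease on each
    other disease with doubly-robust targeted maximum likelihood estimation
    (TMLE) and influence-curve inference; ranks influential and influenced
    diseases; clusters consequential-spectrum rays and causal-spectrum rings
    with Ward linkage and multiscale-bootstrap approximately-unbiased (AU)
    cluster support; classifies bi- and uni-directional progression and tests
    ICD-10 chapter crossing against a permutation null; partitions the
    thresholded progression graph into constellations with self-tuning
    spectral clustering, hub identification, Kamada-Kawai layout and adjusted
    Rand index stability checks. A sex-stratified synthetic-cohort simulator
    with a planted causal graph provides ground-truth effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    ape,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
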