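Package: capnoseq
Title: State Sequence Analysis of Capnography Monitoring During Procedural Sedation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of per-second capnography-derived respiratory monitoring
    collected during procedural sedation. Each second of a procedure is
    classified into a categorical respiratory state (normal breathing,
    hypopneic hypoventilation, bradypneic hypoventilation, apnea) from
    respiratory rate, end-tidal CO2 and waveform amplitude cut-offs; pairwise
    chi-squared and Euclidean dissimilarities between patients' state
    sequences are computed from state occupancy distributions; Ward
    hierarchical clustering derives a typology of common sequence patterns;
    and multivariable distance matrix regression with permutation inference
    quantifies how much of the between-patient sequence dissimilarity is
    explained by demographic and clinical covariates. A semi-Markov synthetic
    cohort generator with known ground truth supports validation of the whole
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
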