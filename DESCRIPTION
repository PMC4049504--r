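Package: crosscourse
Title: Cross-Cell-Type Analysis of Stimulation-Response Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparing transcriptional responses to a
    stimulus (such as TGF-beta 1) across cell types and species from short
    expression time courses. Provides empirical-Bayes posterior probabilities
    of whole-time-course differential expression, per-timepoint moderated
    testing, model-based clustering of log fold-change curves with BIC model
    selection, Wang-measure GO semantic similarity between clusters,
    ranking-score logistic gene-set association tests with commonality and
    reproducibility statistics, simplified de-novo promoter motif discovery
    with PWM library matching, homolog-mediated cross-species set projection,
    and node-weighted interactome shortest-path analysis. A synthetic-study
    generator with known ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    sva,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
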