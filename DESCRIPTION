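Package: callgram
Title: Combinatorial Structure of Primate Alarm-Call Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial call sequences of the Olive
    colobus monkey (Procolobus verus): a calibrated synthetic corpus
    generator, call-type clustering by Partitioning Around Medoids with
    silhouette-based selection of the number of clusters, sequence
    segmentation from a Gaussian mixture on log inter-call intervals with
    bootstrap likelihood-ratio selection of the number of modes, prefix-trie
    and rule-based grammar analysis of call sequences, and context-specificity
    inference with Poisson random-intercept mixed models (Laplace
    approximation, optional Gaussian ridge on fixed effects, parametric
    bootstrap confidence intervals, marginal-means contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mvtnorm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    emmeans,
    lme4,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
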