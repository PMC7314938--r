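Package: mmibn
Title: Mixed Mutual Information Variable Selection and Bayesian Network
    Modeling for Multimodal Genomic Data
Version: 0.1.0
Authors@R:
    person("mmibn", "maintainers", email = "mmibn@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of multimodal molecular data (binary somatic
    mutation, continuous expression and promoter methylation) against
    discrete clinical outcomes. Stage one ranks genes by mixed-type mutual
    information between each gene's (S,E,M) vector and the outcome, using a
    k-nearest-neighbour estimator valid for discrete/continuous mixtures,
    and selects genes by an empirical-CDF quantile or threshold. Stage two
    discretizes the selected variables by maximum-entropy (equal-frequency)
    binning, learns a discrete Bayesian network with a sparse-candidate
    restricted greedy search under the BDeu score, extracts the Markov
    neighbourhood of the outcome node, and augments its edges with
    two-sample Kolmogorov-Smirnov and Fisher exact test p-values. Includes a
    synthetic multimodal data generator with planted effects so the whole
    pipeline is testable without access to patient-level archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
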