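Package: chemscreen
Title: Network-Based Screening of Candidate Drugs from Chemical and
    Protein Interaction Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step guilt-by-association screen for candidate drugs
    built on chemical-chemical and protein-chemical interaction scores in
    the STITCH detailed-links dialect. Candidate compounds are first
    required to interact with at least one approved drug, then filtered by
    an association test against disease-related chemicals and genes
    together with a permutation test that assigns empirical P-values to
    mean interaction ("rating") scores, with thresholds derived from the
    approved drugs themselves. Survivors are encoded as fifteen
    mean-interaction-score features and co-clustered with the approved
    drugs by a diagonal-covariance Gaussian mixture model fitted by
    expectation-maximization, with the number of components selected by
    cross-validated likelihood; compounds sharing the drugs' cluster over
    iterated rounds are reported as putative candidates. Includes a
    synthetic fixture generator with planted ground truth, a pipeline
    orchestrator with subnetwork export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
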