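Package: mfclone
Title: Clonality-Aware Single-Cell Analysis of Cutaneous T-Cell Lymphoma Progression
Version: 0.1.0
Authors@R: person("mfclone", "maintainers", email = "mfclone@example.org", role = c("aut", "cre"))
Description: Tools for combined single-cell RNA and T-cell receptor (TCR) repertoire
    analysis of cutaneous T-cell lymphoma skin lesions. Groups cells into clonotypes
    from CDR3 amino-acid sequences with allelic-exclusion-aware merging, identifies the
    dominant (putatively malignant) clone per patient, gates benign T-cell subsets by
    canonical markers, performs logistic-regression likelihood-ratio differential
    expression with Bonferroni correction, intersects per-patient results into a
    direction-consistent cross-patient marker panel, and scores ligand-receptor
    interactions between the malignant clone and microenvironment clusters with a
    cluster-label permutation null and Benjamini-Hochberg FDR. Ships a negative-binomial
    synthetic-data generator that emulates the paired-lesion study design so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
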