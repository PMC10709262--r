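Package: scstate
Title: Cell-State Resolution for Xenograft Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("scstate", "maintainers", email = "scstate@example.org",
    role = c("aut", "cre"))
Description: An analysis chain for resolving biological cell states in
    tumour/metastasis single-cell RNA-seq from patient-derived xenografts:
    species-ratio, read-depth and gene-band library QC; five-stage cell-cycle
    scoring with correlation-based assignment, iterative profile refinement
    and a continuous circular phase; per-gene GLM removal of cell-cycle and
    library-complexity covariates; PCA, shared-nearest-neighbour graphs and
    Louvain clustering; pairwise marker detection with Holm-corrected
    combined p-values; preranked gene-set enrichment with permutation NES,
    supercluster identification and signature extraction. Ships a
    negative-binomial simulator with planted donor, state, cell-cycle and
    capture-efficiency structure so the whole chain is testable against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
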