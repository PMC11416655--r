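Package: ferrotarget
Title: Integrated Discovery of Candidate Ferroptosis Suppressor Genes
Version: 0.1.0
Authors@R:
    person("Dana", "Rechavi", email = "maintainer@ferrotarget.org", role = c("aut", "cre"))
Description: An integrated target-discovery pipeline for ferroptosis suppressor
    genes. Combines (i) Pearson correlations of gene expression and CRISPR gene
    dependency with drug-vulnerability AUCs derived from log-logistic
    dose-response fits and (ii) transcriptomic similarity between gene-knockdown
    perturbation signatures and ferroptosis-inducer response profiles, scored by
    a competitive (CAMERA-style) gene-set test. The resulting predictor matrix
    is projected to two dimensions with UMAP and candidate suppressors are
    ranked by Euclidean distance to anchor genes. Includes preranked GSEA and
    ssGSEA validation utilities, an offline citation-based validation module,
    and a fully synthetic benchmark generator with planted ground-truth
    suppressors so the complete pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    uwot
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
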