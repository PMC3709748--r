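Package: mirpin
Title: Discovery of miRNA-Regulated Protein Interaction Networks in Tumor Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering microRNA-regulated
    protein-protein interaction networks from two-group (normal versus
    tumor) expression profiles. Differentially expressed miRNAs and mRNAs
    are selected with a SAM-style permutation statistic, paired by opposite
    expression trend with multi-database target-prediction consensus,
    expanded into per-miRNA interaction networks through a reference
    protein-protein interaction map, and characterized by level-filtered
    hypergeometric Gene Ontology enrichment with Benjamini-Yekutieli false
    discovery rate control and a cancer-keyword classifier. Candidate
    marker miRNAs are evaluated by ROC analysis with the Hanley-McNeil
    standard error. A synthetic-data module generates every pipeline input
    with planted ground truth, and the transcribed result tables of the
    original breast-cancer study are packaged as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
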