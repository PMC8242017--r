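Package: bionetval
Title: Network-Based Evaluation of Biomedical Named-Entity Recognition Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates biomedical named-entity recognition (bio-NER) tools
    without annotated corpora. From per-tool disease-entity association
    tables it builds weighted disease-disease similarity networks (Jaccard
    similarity of entity profiles with a percentile edge filter), measures
    their node and edge overlap with omics reference networks (disease-gene,
    disease-protein, disease-drug) and the coincidence of their Louvain
    communities with top-level disease-classification categories, attaches
    z-scores against Erdos-Renyi G(n,m) null models, and ranks tools by a
    min-max-normalized composite of the two significance scores. Includes a
    synthetic-world generator with planted category structure so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
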