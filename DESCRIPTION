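Package: homologNS
Title: Network-Similarity Scoring of Functional Analogs Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies functional analogy among cross-species homologs from
    gene-expression compendia alone. Per-species functional-relationship
    networks are built by naive-Bayes integration of expression datasets
    against a Gene Ontology derived gold standard; gene neighborhoods are
    projected onto species-independent meta-genes (gene families) and the
    network-similarity (NS) score between two genes is the hypergeometric
    tail probability of their meta-gene neighborhood overlap, computed
    against an organism-pair-specific family background. Includes overlap
    decomposition, family-level GO enrichment with FDR control, a pooled
    normalized-rank AUC evaluation framework for homolog ranking, and a
    synthetic two-species compendium generator with planted co-expression
    modules for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'neighborhoods.R'
    'nsScore.R'
    'enrichment.R'
    'evaluation.R'
    'integration.R'
    'goldStandard.R'
    'synthetic.R'
    'io.R'
    'cli.R'
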