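Package: phenofun
Title: Linking Cellular Loss-of-Function Phenotype Profiles to Gene Function
Version: 0.1.0
Authors@R:
    person("phenofun", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for relating ontology-annotated loss-of-function
    phenotypes from RNAi screens to Gene Ontology cellular-process
    function. Provides an OBO ontology reader with annotation
    propagation and information-content computation, fifteen phenotypic
    similarity measures on binary gene-by-phenotype profiles (vector,
    character, frequency and ontology semantic measures, including
    logistic-PCA-reduced variants), a protein-interaction benchmark
    (ROC AUC, nearest-neighbour recovery with hypergeometric
    significance), per-phenotype functional-coherence permutation tests
    with Benjamini-Hochberg correction, and an annotation-driven
    definition of functions as clusters of ontology terms obtained by
    bipartite projection and normalized-cut spectral clustering. A
    synthetic-data generator with planted gene modules makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
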