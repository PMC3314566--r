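Package: stabmark
Title: Stability-Aware Biomarker Discovery with Biological Prior Knowledge
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a stability-aware biomarker discovery workflow for
    two-class transcriptomics experiments. Biological prior knowledge
    (Gene Ontology semantic similarity, protein-protein interaction network
    topology, and expression dependency across a compendium) is encoded as
    feature-feature similarity matrices; expression profiles are linearly
    embedded through the associated row-stochastic matrix so that similar
    features are mapped close together; features are ranked by a
    bootstrap-averaged perceptron ensemble in the style of a Bayes point
    machine; and the reproducibility of the resulting ranked biomarker lists
    is quantified with the normalized Canberra distance. Seeded synthetic-data
    generators with block ground truth make the full pipeline testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, GeneExpression, Network, GO
RoxygenNote: 7.3.3
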