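Package: chemopath
Title: Pathway-Centric Mining of Tumor-Cell Chemoactivity and Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links constitutive tumor-cell gene expression to small-molecule
    growth-inhibition (GI50) chemoactivity on an NCI60-style cell panel.
    Chemoactivity profiles are clustered with a self-organizing map tolerant
    of missing values; every pathway receives a signed Kruskal-Wallis H-score
    at every map node from gene-to-codebook Pearson correlations; candidate
    genes from top-scoring pathways are trimmed by an iterative two-step
    Student's t-test into four expression/sensitivity classes; trimmed panels
    are evaluated by cross-validated Fisher linear discriminant analysis and
    annotated by hypergeometric gene-set overlap enrichment. A synthetic
    panel generator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Pathways, Clustering, Classification, Pharmacogenomics
RoxygenNote: 7.3.3
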