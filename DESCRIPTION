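Package: coexgo
Title: Gene Clustering by Integrating Gene Ontology Annotations into
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised gene clustering that actively combines expression
    data with Gene Ontology annotations.  Each biological function is
    decomposed into coexpressed biological functions by hierarchical
    clustering of its genes on a correlation distance; the resulting binary
    matrix defines a chi-square (correspondence-analysis) distance between
    genes, so that two genes are close only if they are both coexpressed and
    share functional annotations.  Clusters are scored by a coexpression
    indicator (mean pairwise correlation) and a biological homogeneity
    indicator (derived from Cramer's V), each with a size-matched permutation
    p-value.  Includes a paired expression/annotation simulator and benchmark
    comparators (heatmap-style hierarchical clustering and topological-overlap
    network clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
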