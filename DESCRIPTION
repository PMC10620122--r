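Package: gadriver
Title: Personalized Cancer Driver Gene Sets via Network Propagation and
    Genetic Algorithm Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies, for each cancer individual, the subset of
    genetically altered genes (copy-number altered or mutated) whose
    propagated influence over a co-expression-weighted protein
    interaction network best explains that individual's dysregulated
    cancer hallmarks. Network influence is quantified by random walk
    with restart on a column-stochastic transfer matrix whose edge
    weights are absolute Pearson correlations of expression; hallmark
    dysregulation is scored by gene set enrichment analysis (GSEA) of
    per-individual fold changes; subsets of candidate drivers are
    searched with a genetic algorithm whose fitness is the Pearson
    correlation between propagation-derived hallmark enrichment scores
    (Dscores) and expression-derived enrichment scores (Escores),
    both computed by single-sample GSEA. Includes a synthetic cohort
    generator with planted driver genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    data.table,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
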