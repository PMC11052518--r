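Package: ecomena
Title: Community Diversity and RMT-Thresholded Co-Occurrence Networks for
    Amplicon Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Community-level analysis of amplicon sequence variant (ASV)
    count tables as used in host-associated microbiome surveys: rarefaction
    to a common depth, alpha-diversity indices (Shannon, inverse Simpson,
    observed richness, bias-corrected Chao1) with exact Mann-Whitney group
    comparisons, Bray-Curtis and Jaccard dissimilarities, non-metric
    multidimensional scaling, PERMANOVA and MRPP permutation statistics,
    and molecular ecological network analysis: prevalence-filtered Spearman
    correlation networks thresholded by a random-matrix-theory criterion
    (nearest-neighbour eigenvalue spacing test against the Poisson
    distribution), greedy modularity module detection, network summary
    statistics, and Zi/Pi keystone-taxon classification. Includes a
    synthetic-data generator with known ground truth (Dirichlet-multinomial
    communities with factorial design effects, and planted correlated ASV
    blocks) so every stage can be validated without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
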