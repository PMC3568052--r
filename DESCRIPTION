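Package: popsens
Title: Sensitivity of Genetic Connectivity Measures to Unsampled and Under-Sampled Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how site-based landscape-genetic analyses respond
    to unsampled and under-sampled locations. Implements pairwise genetic
    differentiation estimators (Weir-Cockerham theta, Jost's D, Euclidean
    allele-frequency distance), population-graph construction with
    conditional-independence edge pruning and conditional genetic distance,
    eigenvector-centrality and PCA-rarity driven subsampling experiments with
    relative-error, effect-size, rank-correlation and Mantel summaries, a
    spatially explicit individual-based gene-flow simulator on barrier cost
    surfaces for isolation-by-resistance studies, and a calibrated generator of
    synthetic microsatellite datasets. Genotypes are read and written in Genepop
    format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
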