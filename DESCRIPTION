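Package: fitscape
Title: Combinatorial Protein Fitness Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of combinatorially complete
    protein fitness landscapes measured by deep mutational scanning. Computes
    wild-type-relative fitness from sequencing count tables, quantifies and
    classifies pairwise epistasis (magnitude, sign, reciprocal sign) with
    detection-limit adjustment rules, enumerates accessible direct mutational
    paths through diallelic subgraphs with path-realization probabilities and
    Gini indices, decomposes subgraph fitness into epistatic orders by
    Walsh-Fourier analysis, detects conversion and detour bypasses of
    reciprocal sign epistasis and verifies when higher-order epistasis is
    required, imputes missing variant fitness with a sparse log-linear model
    fit by L1-penalized regression, and simulates adaptive walks under greedy,
    correlated and equal fixation models on the directed fitness graph,
    optionally under standard genetic code constraints. Includes a synthetic
    landscape generator with known ground-truth epistatic structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
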