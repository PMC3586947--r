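Package: coexnet
Title: Co-Expression Networks from Correlation, Mutual Information and
    Regression Association Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs weighted gene co-expression networks from a family of
    pairwise association measures and compares them on a common footing.
    Implements the biweight midcorrelation with outlier-proportion capping,
    equal-width discretization with plug-in and Miller-Madow entropy
    estimators, mutual information and its likelihood-ratio-test identity,
    three entropy-normalized mutual-information adjacencies (symmetric
    uncertainty and two universal versions), an empirical cor-MI function
    that predicts the mutual-information adjacency from a correlation
    coefficient, polynomial and cubic-spline regression R-squared association
    measures, hard/soft thresholding and the topological overlap matrix
    transformation, the RELNET, CLR, MRNET and ARACNE network inference
    algorithms, average-linkage module detection with Rand-index evaluation,
    and seed-deterministic simulation benchmarks with linear and quadratic
    gene-gene relationships.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
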