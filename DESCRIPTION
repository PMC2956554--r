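Package: barcodegap
Title: Evaluation of DNA Barcoding Markers by Distance, Similarity and
    Tree-Based Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating candidate DNA barcoding markers in
    closely related plant groups such as the duckweeds (Lemnaceae).
    Computes pairwise Kimura 2-parameter and uncorrected p-distances with
    pairwise gap deletion and minimum-overlap enforcement, summarizes
    intra- and inter-specific divergence and the barcoding gap with
    Mann-Whitney U, Mood's median and Wilcoxon signed-rank tests,
    performs best-match and best-close-match species identification with
    a 95th-percentile intraspecific threshold, scores species monophyly
    on UPGMA and maximum-parsimony trees with bootstrap support, and
    provides in-silico PCR utilities plus a fully seeded synthetic
    marker-sequence generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
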