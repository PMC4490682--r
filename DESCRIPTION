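Package: popcnv
Title: Population-Scale Copy Number Variant Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of copy number variant (CNV)
    calls from SNP genotyping arrays. Implements probe suitability filtering
    (restriction-site and positional-overlap screens, inter-probe distance
    statistics), sample- and call-level quality control, recurrent CNV region
    construction by reciprocal-overlap graph clustering, complex-region
    classification by boundary concordance, permutation-based genomic feature
    enrichment with order-statistic confidence intervals, gene overlap
    classification and subspecies-private CNV detection, SNP- and CNV-state
    genetic distances with neighbor-joining trees, principal coordinates and
    Mantel tests, heterozygosity-based false discovery estimation for deletion
    calls, and a synthetic panel generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    igraph,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
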