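Package: vqfam
Title: Evolutionary Analysis of VQ-Motif Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the expansion and evolution of plant
    VQ-motif gene families. Identifies motif-containing genes in a proteome
    with a position-specific scoring profile and shuffle-calibrated empirical
    E-values; classifies the mechanism of family expansion (tandem array,
    segmental duplication, mobile-element capture, retrogene) from gene
    coordinates, homologous anchor pairs and element annotations; estimates
    Ka, Ks and Ka/Ks by Nei-Gojobori (1986) counting with a bootstrap
    functional-constraint statistic; detects candidate gene-conversion tracts
    with a Sawyer-style fragment statistic and column-permutation P values;
    counts ancestral units of a species-labeled gene tree at lineage splits;
    and classifies tissue-preferred expression, stress regulation and
    co-expression under twofold / correlation-threshold rules. A synthetic
    data generator plants every class of signal with recorded ground truth so
    the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
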