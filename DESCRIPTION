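Package: chalkmir
Title: Small RNA Analysis of Heat-Stressed Rice Caryopsis: Novel MIRNA
    Discovery, Quantification and Differential Expression
Version: 0.1.0
Authors@R:
    person("chalkmir", "developers", email = "chalkmir@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a caryopsis small
    RNA-seq analysis pipeline: discovery of candidate MIRNA loci from
    mapped sRNA reads, evaluation of hairpin mature/miRNA-star duplexes
    against community annotation criteria (mismatch and asymmetric-bulge
    caps, 2-nt 3' overhangs), processing-precision filtering with
    length-class thresholds, best-hit read attribution to a mature/star
    catalog with CPM normalization, negative-binomial exact-test and
    genotype-by-treatment interaction differential expression, set
    comparison of shared and genotype-specific regulation, and qPCR
    (2^-ddCT) and phenotype utilities. Includes a synthetic-data module
    that plants MIRNA hairpins in toy genomes and simulates
    multi-genotype control/heat sRNA libraries with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
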