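Package: ssrkit
Title: Microsatellite Mining, Diversity Statistics and DNA Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-to-fingerprint toolkit for simple sequence repeat (SSR)
    markers. Mines perfect and compound microsatellites from genome sequences
    under configurable per-motif-length repeat thresholds, classifies motifs
    into reverse-complement equivalence classes, assigns SSRs to genic regions
    (UTRs, exons, introns, intergenic, multi-mapped) from GFF3 annotation,
    extracts primer flanks and validates primer constraints including TP-M13
    tailing, computes co-dominant marker diversity statistics (Na, Ne,
    Shannon's I, Ho, Nei unbiased He, PIC, within-population Hs), clusters
    samples by simple-matching band similarity with UPGMA and cophenetic
    validation, and searches for minimal core-marker sets that uniquely
    fingerprint a sample panel. Includes a synthetic-data generator producing
    genomes with planted SSRs, matching annotations and genotype panels with
    specified allele frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    methods,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
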