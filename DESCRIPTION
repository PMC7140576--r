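Package: splitgenes
Title: Detection and Expression-Based Classification of Split-Gene
    Misannotations Across Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two or more independent annotations of the same (or
    closely related) genomes to flag split-gene misannotations, cases where
    one annotation models a locus as a single gene while another models it
    as two or more genes. Candidate loci are identified from whole-genome
    alignment blocks plus reciprocal transcript BLAST (syntenic homology),
    filtered for tandem duplicates, strand and overlap inconsistencies, and
    expression support. Each testable candidate is then scored with the M2f
    statistic, the mean absolute log2 fold change in exon-averaged TPM
    between the component genes across RNA-seq libraries, and classified
    against empirical null distributions built by artificially splitting
    single genes and pairing adjacent distinct genes. Includes a synthetic
    data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
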