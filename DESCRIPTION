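Package: neuroedit
Title: Comparative A-to-I RNA Editing Analysis Across Neuronal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of adenosine-to-inosine (A-to-I) RNA
    editing across cell populations measured by RNA-seq or targeted amplicon
    (mmPCR-seq) sequencing. Provides de novo editing-site discovery from base
    counts with a configurable filter cascade, editing-level quantification with
    coverage and reproducibility filtering, pairwise differential editing via
    Fisher's exact tests on allele counts, population-specific site calling by
    replicate z-scores, and clustered-site editing-isoform (read-backed
    haplotype) analysis against an independence null, including a
    sequential-editing model. A beta-binomial synthetic-data generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    yaml,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
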