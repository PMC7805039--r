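Package: gwasvcfkit
Title: Convert, Harmonise, Index and Query GWAS Summary Statistics as GWAS-VCF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for storing genome-wide association study (GWAS) summary
    statistics in the GWAS-VCF convention: reads heterogeneous tabular
    summary statistics under a user-supplied column schema, harmonises
    alleles against a reference genome so the non-effect allele always
    matches the reference sequence, left-aligns and trims insertion-deletion
    variants, splits multiallelic sites, sorts karyotypically, writes
    BGZF-compressed VCF 4.2 with tabix and rsid indexes, and supports
    interval, position, rsid and P-value queries plus tabular export and
    multi-trait merging. A deterministic synthetic-data generator produces
    reference genomes and summary-statistics tables with a ground-truth
    ledger so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    Rsamtools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
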