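Package: famlof
Title: Familial Germline Loss-of-Function Variant Prioritization and
    Burden Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcript-aware consequence prediction for germline rare
    variants (canonical splice disruption modelled as exon skipping with
    premature-termination-codon and nonsense-mediated-decay calls,
    stop-loss readthrough extension), pedigree-based germline quality
    control and segregation assessment, cross-family recurrence
    prioritization of putative loss-of-function genes, and gene-based
    carrier-collapsing case-control burden tests with a synonymous-mask
    bias calibration. Ships a deterministic synthetic-cohort simulator
    (reference contigs, transcript models, multi-generation pedigrees
    with an incompletely penetrant dominant risk allele, and case-control
    genotype matrices with read-depth-resolved genotypes) so the whole
    pipeline runs from standard FASTA/GFF3/VCF/PED inputs it generates
    itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
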