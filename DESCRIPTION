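Package: superpan
Title: Super-Pangenome Gene-Family, Structural-Variant and Allele-Specific
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Pangenome", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for haplotype-resolved
    super-pangenomes of plant genera. Classifies gene families into
    core, softcore, dispensable and private categories from orthogroup
    occupancy, computes pan/core saturation (rarefaction) curves,
    parses whole-genome-alignment structural-variant tables (SyRI
    dialect), bins SV lengths, screens SV-overlapping genes, detects
    highly diverged regions between haplotypes, calls allele-specific
    expression from paired-allele TPM matrices with cross-condition
    consistency classification, assigns unique gene-duplication modes
    by priority, estimates genome size from k-mer spectra, and dates
    LTR retrotransposon insertions. A synthetic-data generator with
    planted ground truth makes every stage testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    data.table,
    jsonlite,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
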