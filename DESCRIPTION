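Package: snvconcord
Title: Concordance of Single Nucleotide Variant Detection Across Sequencing Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares single nucleotide variant (SNV) call sets produced by
    different massively parallel sequencing assays (PCR-free whole-genome,
    exome capture, and targeted panel enrichment) within shared capture
    regions. Implements pairwise classification of fully exclusive (FE) and
    high-quality fully exclusive (HQFE) variants, three-way missed-variant
    confirmation and sensitivity estimation, coverage and per-gene
    low-coverage reporting with ACMG secondary-findings flags, GC-content
    diagnostics, allele-balance/read-depth stratification with trend tests,
    and a calibrated three-platform simulator that generates truth sets,
    depth tracks, and VCFs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
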