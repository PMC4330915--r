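Package: rcprofiler
Title: Copy-Number Variant Detection from Read Depth Using Reference
    Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy-number variants (CNVs) in whole-genome
    sequencing data from depth of coverage. Per-base depth is condensed
    into a compact one-byte-per-20-bp track, stratified into 25 rank-based
    %GC buckets, scaled to a cohort-wide target coverage vector, and
    normalized against a Reference Coverage Profile (RCP): a per-kilobase
    estimate of the diploid coverage level learned from a cohort of
    genomes, robust to common deletions and duplications through
    integer-multiple peak modeling with a Hardy-Weinberg equilibrium
    penalty. Normalized profiles are segmented with a five-state hidden
    Markov model into copy-number states 0-4, and segments are annotated
    with population genotype and allele frequencies, rare-deletion gene
    impact, and Mendelian trio concordance. A synthetic cohort generator
    with known truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
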