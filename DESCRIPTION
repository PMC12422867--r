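Package: hybriddiag
Title: Genomic and Occurrence-Based Diagnosis of Wild F1 Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to confirm a suspected wild F1 hybrid from moderate-coverage
    resequencing data and citizen-science occurrence records. Implements masked
    consensus calling under base- and mapping-quality thresholds, phased
    haplotype-block assignment to candidate parent species with explicit
    tie handling, ancestry-informative-marker discovery at an allele
    frequency difference threshold with hybrid index and interclass
    heterozygosity (triangle) statistics, windowed per-site heterozygosity
    with a synthetic-hybrid contrast, and checklist-based co-occurrence
    filtering, spatial thinning, presence/absence threshold selection and
    niche-overlap accounting. A seeded synthetic-data generator produces
    parental lineages, pedigreed diploids, pileups, phase blocks and
    checklist tables with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
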