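Package: chtriage
Title: Clonal Hematopoiesis Triage for Paired cfDNA and White-Blood-Cell Panel Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies clonal hematopoiesis (CH) mutations from paired plasma
    cell-free DNA (cfDNA) and peripheral-blood-lymphocyte (PBL) panel sequencing
    call tables. Each called variant is triaged into somatic, pathogenic
    germline, or candidate-CH classes using depth, variant-allele-fraction and
    population-frequency rules together with a two-sided Fisher's exact test on
    the paired allele counts; candidate CH is then funnelled through minimum
    alt-read, cohort carrier-ratio and matched-tumor crosscheck filters.
    Cohort-level analytics cover age-group prevalence trends, per-gene carrier
    summaries, two-cohort per-gene comparison, CH-/germline-/somatic-preferred
    mutation and gene classification, overlap with actionable-mutation
    knowledge bases, and generic gene-set over-representation. A synthetic
    paired-cohort generator with ground truth provides a calibrated test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
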