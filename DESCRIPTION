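Package: triotriage
Title: Phased Trio Genome Variant Prioritisation for Rapid Rare-Disease
    Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tiered prioritisation of candidate disease variants from
    trio (proband plus both parents) whole-genome sequencing, as used in
    rapid diagnostic workflows for critically ill children. Implements
    population-frequency and consequence filtering (including a
    permissive high-carrier-frequency rule for recessive and X-linked
    candidates), the four trio inheritance models (de novo, autosomal
    recessive homozygous, autosomal recessive compound heterozygous with
    trio trans-phasing, and X-linked), HPO-driven bespoke gene panels
    with phased escalation from a patient-specific panel through
    disease-gene panels to the whole genome, an opt-in secondary
    findings scan, ranked candidate reporting, and a synthetic
    annotated-trio cohort generator for end-to-end validation without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    dplyr,
    tibble,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
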