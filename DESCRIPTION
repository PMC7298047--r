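Package: repurpose
Title: Drug Repurposing by Target-Set Enrichment and EMR Prevalence Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational drug repurposing from disease gene sets.
    Assembles disease gene lists from multiple evidence sources with
    provenance, scores every drug in a drug-gene interaction table for
    overrepresentation of its targets in the disease set (Yates-corrected
    chi-squared or Fisher exact test with Benjamini-Hochberg FDR control),
    bridges disease-to-drug-to-gene maps, aggregates per-source rankings into
    a consensus candidate list, and screens candidate drugs against electronic
    medical records by comparing cohort glaucoma prevalence to a fixed
    background prevalence (odds ratio and chi-squared P against an assumed
    reference cohort). Includes seeded generators for synthetic interaction
    tables and patient cohorts with planted effects, for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
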