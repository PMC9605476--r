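Package: panelscreen
Title: Candidate-Gene Panel Screening for Non-Syndromic Tooth Agenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a candidate-gene panel analysis
    for non-syndromic tooth agenesis: a rule-based rare-variant
    filtering/prioritization/classification cascade with an auditable trail
    (minor-allele-frequency cut-off with a gene allowlist, likely-gene-disrupting
    rules, an in-silico pathogenicity consensus vote, gene-category and pLi
    prioritization, and ClinVar/HGMD-driven pathogenic versus likely-pathogenic
    labelling), dental phenotype accounting in FDI notation
    (hypodontia/oligodontia classification, tooth-class distributions,
    carrier summaries and oligogenic co-occurrence detection), a common-variant
    case-control association stage (Cochran-Armitage trend test, allelic odds
    ratios with Woolf confidence intervals and Haldane-Anscombe correction,
    Bonferroni multiplicity control), and a seeded synthetic cohort generator
    so that every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    yaml
Config/testthat/edition: 3
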