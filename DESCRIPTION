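Package: linkbox
Title: Deterministic Record Linkage Between a Clinical Cohort and an HIV Surveillance Registry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for deterministic, multi-level record linkage
    between a clinical cohort and an HIV surveillance registry. Implements a
    scored matching cascade over name, date of birth, Social Security number,
    birth sex and study identifier (with alias-name handling and a sharing
    threshold), Cohort-ID filter reconciliation, cross-site deduplication,
    recipient-redacted report generation, laboratory and demographics
    discrepancy comparison, a seeded synthetic identity generator with
    ground-truth labels, and validation metrics (precision by score band) for
    threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
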