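Package: pcidw
Title: Text Mining of Coronary Intervention Reports and Stent Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dictionary-driven pattern extraction of per-vessel stent records
    from semi-structured percutaneous coronary intervention (PCI) procedure
    reports, with the validation machinery needed to trust the extraction
    (pair-level confusion metrics, Cohen's kappa between extractor outputs,
    three-way consensus merge with manual adjudication), assembly of a
    vessel-level analysis warehouse (target vessel revascularization outcome,
    covariate derivation, mixed-category exclusions), and Kaplan-Meier /
    Cox proportional-hazards comparisons of stent classes. A synthetic
    report-corpus and cohort generator with a known proportional-hazards
    model makes the whole pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
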