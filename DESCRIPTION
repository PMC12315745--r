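Package: bidscurate
Title: Level-1 Curation Tools for BIDS Neuroimaging Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating multi-study neuroimaging datasets organised
    under the Brain Imaging Data Structure (BIDS). Provides subject-level
    hierarchical phenotype storage with variable aliases and provenance and
    regeneration of BIDS phenotype tables; pseudonymization transforms (date
    anchoring to study day zero, quarter-hour scan-time quantization,
    deterministic recoding of institutions, scanner serials and participant
    IDs) with sidecar-metadata scrubbing and residual-identifier auditing; a
    BIDS filename grammar with failed-QC marking and 1-5 QC rating records;
    dataset roster accounting (participants, sessions, scans by modality)
    with cross-dataset aggregation; balanced template-cohort selection
    stratified by site, sex, clinical status and age decade; and a
    synthetic-fixture generator producing toy BIDS studies with known ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
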