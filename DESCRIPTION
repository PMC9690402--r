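Package: ctscreen
Title: Opportunistic Screening Biomarkers from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pulmonary, cardiovascular, metabolic and
    musculoskeletal imaging biomarkers from chest(-abdomen) CT volumes with
    accompanying anatomical label maps: per-compartment Agatston and volume
    calcium scores, single-slice fat planimetry and liver steatosis grading,
    lung densitometry with parametric response mapping and Pi10 airway
    summaries, pulmonary nodule measurement with Lung-RADS categorization,
    and phantom-calibrated trabecular bone mineral density with T-scores.
    Results are banded against reference ranges (green/yellow/red) and
    assembled into a structured report. A seeded synthetic phantom generator
    with an analytic ground-truth manifest makes every analyzer testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
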