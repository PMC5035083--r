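Package: drtriage
Title: Red-Green-Yellow Referral Triage for Diabetic Retinopathy from
    Single-Field Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a rule-based red-green-yellow triage algorithm that
    maps structured per-eye grading forms from single-field 45-degree
    posterior-pole fundus photographs to a referral interval (immediate,
    6-month review, 1-year review), together with the fundus geometry used
    to aggregate point lesion annotations into forms (anatomical quadrants
    around the disc, macular circles at 1 and 2 disc diameters from the
    fovea), and the reader-study validation machinery: one-vs-rest
    confusion tables, Cohen's kappa with large-sample standard errors and
    agreement bands, sensitivity and specificity with Wilson score
    confidence intervals, single-operating-point AUC and subgroup
    comparison, chi-square effect-size sample-size estimation, and a
    multi-reader study simulator with per-reader confusion matrices and
    missing responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
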