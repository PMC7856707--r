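Package: regilink
Title: Record Linkage Between Clinical Registries Using the SLK-581
    Statistical Linkage Key
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links episode-level records between a fully identified surgical
    registry and a deidentified intensive-care registry carrying the
    Australian Institute of Health and Welfare 14-character statistical
    linkage key (SLK-581). Implements four linkage strategies: probabilistic
    matching with additive field agreement weights and a procedure-date
    caliper; staged deterministic matching on non-identifying variables
    (9 stages); SLK-581 plus admission date alone; and staged deterministic
    matching augmented with SLK-581 (12 stages). Includes a calibrated
    synthetic dual-registry generator with a known gold standard, and
    evaluation utilities (match rates, false positives and negatives,
    cohort-characteristic comparisons, between-strategy tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
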