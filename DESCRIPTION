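Package: ctdoseaudit
Title: CT Dose Metrics and Dose-Monitoring-System Auditing
Version: 0.1.0
Authors@R: person("CT Dose Audit", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computation and auditing of CT dose metrics from per-series dose
    records: effective dose (ED) from dose-length product with region-specific
    conversion factors, weight-corrected size-specific effective dose (SED),
    size-specific dose estimate (SSDE) from patient effective diameter, and SED
    estimated from SSDE via published region- and scan-length-specific linear
    regressions. Includes emulation of the fixed-body-region misassignment
    failure mode of commercial dose-monitoring systems, region-stratified
    slope comparison with absolute percent differences, a seeded two-scanner
    synthetic cohort generator, and an end-to-end audit pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
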