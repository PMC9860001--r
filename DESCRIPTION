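Package: htcomplexity
Title: Complexity Metrics for Helical Tomotherapy Plan Sinograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts plan-complexity metrics from helical tomotherapy (HT)
    delivery sinograms: delivery parameters, absolute and fractional
    leaf-open-time (LOT) distribution statistics, per-projection field
    geometry scores based on connected open-leaf components, and sinogram
    modulation and variability indices. Reads HT plans from DICOM RT-Plan
    files (Precision and RayStation dialects) or a plain-JSON exchange
    format, generates synthetic plans with controlled statistical structure,
    batches extraction of a 65-metric registry to CSV, and provides
    cohort-level analyses: Spearman metric-metric correlation maps with
    graded classes, redundancy-aware screening of metrics against
    patient-specific QA passing rates, and delivery-efficiency
    stratification of cohorts by the CFNS75 score with t-tests and pooled
    fractional leaf-open-time histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
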