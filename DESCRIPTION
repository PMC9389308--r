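Package: growthbands
Title: LMS Growth-Reference Standardization and Dual-Chart Band Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes pediatric anthropometry (weight, height, BMI) against
    tabulated LMS (Box-Cox) growth references, converts standard deviation
    scores to centiles, classifies children into percentile bands
    (underweight/normal/overweight/obesity and growth-deficiency/normal/high
    growth), and compares the band distributions a cohort receives under two
    interchangeable references - a general-population chart and a
    condition-specific chart such as a Down-syndrome reference - with
    percentage-point differences and chi-squared tests. Includes a synthetic
    reference and cohort generator so the whole pipeline can be exercised and
    validated without access to copyrighted reference tables or patient data,
    and a small command-line front end for reproducible file-based runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
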