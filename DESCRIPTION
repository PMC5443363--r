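Package: youthbmi
Title: BMI-for-Age Metrics, Severe Obesity Classification, and Growth
    Charts for Children and Adolescents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sex- and age-specific body mass index (BMI)
    percentiles, z-scores, and BMI as a percent of the 95th percentile for
    youth aged 2 to <20 years from an LMS (lambda-mu-sigma) reference
    table; classifies each subject into one of six mutually exclusive
    weight-status categories, including severe obesity classes 2 and 3
    defined by dual percent-of-95th-percentile and absolute-BMI criteria;
    and renders sex-specific cross-sectional and longitudinal BMI-for-age
    charts with standard and severe-obesity percentile curves to EPS or
    PDF. Includes a synthetic reference and cohort generator with known
    ground truth for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    utils
Suggests:
    withr,
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
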