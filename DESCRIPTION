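Package: burdenr
Title: Burden of Disease Estimation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for national burden of disease studies: redistribution
    of deaths coded to ill-defined causes (direct evidence, indirect
    multiple-causes-of-death, and proportional methods, with cascade
    resolution and conservation audits), fatal and non-fatal burden
    computation (years of life lost, years lived with disability,
    disability-adjusted life years), Sullivan-method health-adjusted life
    expectancy, risk-factor attribution via population attributable and
    potential impact fractions, a two-dimension A-E data/methods quality
    index, and a synthetic-data generator that emulates a national
    multiple-cause mortality database extract so every stage is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
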