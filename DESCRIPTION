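Package: vesselastica
Title: Pressure-Strain Loop Biomechanics for Tissue-Engineered Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mechanical remodeling of in-situ
    tissue-engineered vasculature (iTEV) from intravascular ultrasound
    (IVUS) data. Extracts time-resolved circumferential strain from lumen
    contours, pairs it with intraluminal pressure into pressure-strain
    (P-S) loops, estimates the wall elastic modulus from the loop, and
    summarises remodeling as a regeneration score that compares the
    graft's modulus to the native vessel, normalized to the difference at
    implantation. Also fits first-order hydrolysis kinetics to scaffold
    tensile-strength and molecular-weight decay series, generates
    ground-truth-known synthetic phantoms and cohorts for validation, and
    reproduces the variance-screened two-group and many-to-one group
    comparison protocol used in such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
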