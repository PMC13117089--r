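Package: echolith
Title: Rule-Based Stone Detection and Posterior Acoustic Shadow Localization in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable, rule-based pipeline that detects kidney and
    gallbladder stone candidates inside a clinician-drawn region of interest of a
    B-mode ultrasound frame, verifies them through posterior acoustic shadow
    analysis, ranks them with a composite score, and localizes the shadow region
    beneath the selected stone. Includes morphological top-hat candidate
    enhancement, local-contrast and shadow-region screens, shape penalties,
    a confidence-stratified evaluation protocol (point-to-axis localization
    error, acceptance accuracy, t-based confidence intervals, two-observer
    intraclass correlation), an ablation runner, and a seeded speckle-phantom
    generator with exact ground truth for fully reproducible experiments.
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
    grDevices,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    png,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
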