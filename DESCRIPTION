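Package: woo
Title: Windows of Opportunity for Establishment in Fluctuating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the establishment of young organisms in
    temporally variable environments through the windows-of-opportunity
    framework. Provides generators for regular dichotomous, dichotomous
    Markov noise (DMN) and Ornstein-Uhlenbeck-type environmental signals,
    stage-dependent tolerance models with linear or exponential growth,
    closed-form theory for critical growth rates, window-length statistics
    and establishment probabilities, Monte-Carlo establishment experiments
    on simulated signals, and reproducible experiment presets with
    structured CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
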