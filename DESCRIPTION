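Package: vvsim
Title: Simulation and Analysis of Vasovagal Responses to Galvanic Vestibular Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying vasovagal-syncope-like responses of anesthetized
    rats to sinusoidal galvanic vestibular stimulation (sGVS). Provides a
    phenomenological simulator of multichannel physiological sessions (stimulation
    current, mean arterial pressure, heart rate, laser-Doppler cerebral blood
    flow) with group-dependent response dynamics, the analysis-window segmentation
    and percent-change-from-baseline summaries used for such recordings, a
    baseline-referenced sustained-drop detector with its drop-delay statistic, a
    stimulus-locked oscillation score and responder inclusion rule, and a balanced
    two-way group-by-time analysis of variance with Sidak-adjusted pairwise
    comparisons. All results are returned as tibbles and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
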