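Package: p300speller
Title: Simulation of a P300 Row-Column Speller for Smartphone Messaging Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of an asynchronous P300 row-column
    speller that drives smartphone messaging through spoken assistant
    commands. Generates synthetic eight-channel EEG with stimulus-locked
    P300 deflections under the paradigm's 224 ms stimulus onset asynchrony,
    applies the online band-pass and notch filter chain, fits a stepwise
    linear discriminant (SWLDA) target/non-target classifier, schedules and
    decides row-column selections, runs the four-menu control state machine
    (no-control, intentional control, spelling with word prediction, and
    confirmation), plans minimum-action task solutions, and computes the
    standard performance metrics: accuracy, information transfer rate,
    written symbol rate, output characters per minute, SUS and Raw NASA-TLX
    scores. A packaged reference table of published per-subject online
    results supports summary reproduction.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
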