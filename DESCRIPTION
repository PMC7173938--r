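Package: chancelevel
Title: Chance-Level Performance Thresholds for Closed-Set Forced-Choice Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact binomial modelling of random guessing in closed-set,
    n-alternative forced-choice tests such as closed-set speech audiometry and
    loudspeaker localization. Computes upper and lower chance thresholds for
    hit rates from the binomial point probability rule, classifies observed
    scores as significantly above chance, chance-consistent, or significantly
    below chance (a statistical flag for malingering or systematic error),
    generates printable threshold tables over grids of alternatives and trial
    counts, and derives chance-level thresholds for root-mean-square angular
    localization error by Monte Carlo simulation of guessing on a loudspeaker
    array. Includes a synthetic responder simulator (guesser, listener,
    malingerer) for studying the operating characteristics of the decision
    rule, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
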