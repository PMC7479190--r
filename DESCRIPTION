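Package: ptdetect
Title: Convergent Detection of Phase Transitions in Short Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects critical transitions (phase transitions, regime shifts)
    in short, noisy, non-stationary time series such as daily self-ratings
    from psychotherapy process monitoring. Seven first-order indicators
    (penalized change-point analysis of mean and variance, dynamic
    complexity, permutation entropy, Stockwell time-frequency analysis,
    instantaneous frequency, moving-window synchronization, and recurrence
    plots) are combined through a second-order change-point layer that pools
    transition estimates across methods and validates their clustering
    against uniform random surrogates. Includes simulators with known
    transition windows (a Henon map with a ramped control parameter and a
    generic regime-shift generator) for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
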