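Package: rivalnorm
Title: Divisive-Normalization Simulator for Chromatic Binocular Rivalry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates perceptual dominance during chromatic interocular-switch
    rivalry with a feature-tuned divisive-normalization model. Dichoptic
    stimulus specifications (fusion box, rivalrous disks, annuli, chromatic
    backgrounds) are turned into pooled, normalized chromatic drives; two
    competing color representations then evolve by stochastic winner-take-all
    comparison with multiplicative gain, truncated-normal signal-proportional
    noise, adaptation of the dominant representation, and recovery of the
    suppressed one. Includes reproducible experiment campaigns with summary
    tables, parameter-sensitivity sweeps, exact binomial staircase-ordering
    statistics for observer report streams, and a synthetic report-stream
    generator for end-to-end testing of the statistics stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
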