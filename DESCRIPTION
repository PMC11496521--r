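Package: spinesound
Title: Sound-to-Spinal-Cord Stimulation Encoding and Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory sensory substitution through a spinal
    computer-brain interface. Converts mono audio into participant-specific
    multi-channel spinal cord stimulation patterns using continuous
    interleaved sampling (band-pass filterbank, envelope extraction, frame
    quantization to discrete intensity levels, and interleaved charge-balanced
    biphasic pulse scheduling). Provides exact information-capacity accounting
    for channel/level/frame-rate configurations, synthetic sound fixtures for
    the experimental stimulus categories, signal-detection and small-sample
    nonparametric statistics for identification and same/different
    discrimination tasks (exact binomial, exact Wilcoxon signed-rank, d-prime
    with extreme-rate correction), and a noisy ideal-observer simulator of the
    identification and discrimination experiments.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
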