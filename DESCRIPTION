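Package: cogtrace
Title: Symbolic Fault Anticipation for Simulated Cognitive Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for symbolic fault anticipation
    in closed-loop brain-machine interface research. Generates EEG-like
    multichannel episodes with parameterised fault injection (gradual intent
    drift, late decision reversal, overload-induced schema collapse) and full
    ground-truth timelines; detects epistemic shifts with a sliding-window
    spectral discriminator (Jensen-Shannon divergence against a baseline
    spectrum, spectral entropy, alpha power, phase-locking synchrony, and a
    matched-filter hypothesis bank); maps detected events to a user-facing
    symbolic vocabulary serialized as JSON-lines traces; and scores traces
    against ground truth (traceability, anticipation latency, per-marker
    statistics, bootstrap confidence intervals) with a batch study runner and
    a grid/random-search calibration helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
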