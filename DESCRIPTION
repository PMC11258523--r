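Package: crowdbline
Title: Gamified Crowdsourced Labeling of Lung Ultrasound B-Lines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for aggregating and evaluating crowdsourced classifications
    of B-lines on lung ultrasound clips collected through gamified labeling
    contests. Implements dynamic labeler quality scoring (trailing-window
    Qscores), quality-filtered majority consensus with vote-lead and
    opinion-cap stopping rules, expert-consensus and leave-one-out reference
    standards with randomized tie-breaking, concordance and agreement
    statistics, vote-proportion ROC curves, Monte Carlo opinion-subsampling
    curves, trailing-window learning curves, and a synthetic crowd simulator
    so the whole pipeline can be exercised without access to a proprietary
    opinion log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
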