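Package: swrpipe
Title: Closed-Loop Sharp Wave/Ripple Detection and CA1 Place-Code Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whether suppressing hippocampal sharp
    wave/ripple (SWR) events during sleep destabilises the CA1 spatial code.
    Provides a digital emulation of an analog closed-loop ripple detector
    (direct and delayed-control modes), a non-stringent offline SWR detector,
    event-triggered multi-taper spectra, occupancy-normalised place-field
    rate maps with sparsity and spatial coherence metrics, between-session
    stability statistics (rate change, rate-map correlation, pairwise
    cofiring similarity, Fisher's Z comparison), per-cell optogenetic
    inhibition testing, and a synthetic-data generator that produces
    trajectories, drifting place-cell ensembles, spike trains, sleep LFP
    with ground-truth ripples and light-pulse suppression, so the whole
    pipeline can be exercised end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
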