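Package: noxep
Title: Simulation and Analysis of Intensity-Matched Nociceptive Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying laser- and contact-heat evoked potentials
    (LEPs/CHEPs) at matched perceived pain intensity. Provides a synthetic
    psychophysical observer and trigger-locked EEG generator with known
    ground truth, a double random staircase (DRS) procedure that matches
    laser energy to a contact-heat pain target on the 0-10 numeric rating
    scale, FIR bandpass preprocessing with epoching and artifact rejection,
    SNR-gated extraction of N1/N2/P2 component latencies and amplitudes,
    pinprick secondary-hyperalgesia aggregation, and the paired statistical
    layer (paired t-tests with Bonferroni family correction, Pearson
    correlation, and two-way average-agreement intraclass correlation)
    assembled into session-level comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
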