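Package: stimconsist
Title: Cross-Session Consistency of Intracranial EEG Stimulation Effects on Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how direct electrical stimulation delivered through
    intracranial EEG electrodes modulates spectral band power, and how
    consistent that modulation is between stimulation sessions of the same
    subject and stimulation site. Implements event-locked segment extraction
    with baseline pseudo-trials, stimulation-artifact channel rejection,
    common-average re-referencing, Welch log band power in the five canonical
    bands, the signed Wilcoxon signed-rank z statistic U as a per
    channel-by-band effect measure, the Fisher-transformed zero-centred
    correlation consistency coefficient with its exclusion-circle consistency
    curve and baseline confidence band, and a bootstrap-ANOVA multiple linear
    regression attributing cross-session consistency to session-pair
    covariates. A seeded synthetic session generator emulating RAM-style
    stimulation recordings makes the whole pipeline testable without any
    clinical data, and a minimal EDF reader/writer round-trips sessions on
    disk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
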