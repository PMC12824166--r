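Package: speechenc
Title: Speech Encoding Analysis for High-Gamma Intracranial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for speech-evoked intracranial (ECoG)
    recordings: high-gamma analytic-amplitude extraction (Hilbert and
    Morlet paths), trial alignment with rank-sum responsivity statistics,
    onset-latency detection at 1-ms resolution with a consecutive-bin
    rule, Gaussian-mixture spatial clustering of electrode coordinates,
    spectrotemporal and semantic receptive-field estimation by normalized
    reverse correlation with cross-validated tolerance regularization,
    and modulation-transfer-function tuning comparisons.  Ships a
    synthetic-data generator (planted receptive fields, latencies,
    spatial clusters and word streams) so the whole pipeline is testable
    without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    mclust,
    cluster,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
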