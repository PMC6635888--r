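Package: phonmap
Title: Growing Self-Organizing Maps for Simulating Early Speech Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the emergence of a syllable action repository during the
    babbling and imitation phases of speech acquisition. A semantic growing
    self-organizing map (S-MAP) and a phonetic growing self-organizing map
    (P-MAP) are linked by a bounded Hebbian association and trained on a
    synthetic monosyllabic model language whose items carry bark-band auditory
    and articulator-distance somatosensory neural representations. Includes
    the stimulus generator, the growing-map engine, the two-map model with
    production and perception modes, the cycle-based training regimen with
    checking processes, and evaluation metrics (node classification,
    phonetic-feature region counting, clustering diagnostics, exact rank-sum
    tests) for comparing training modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
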