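Package: mindsig
Title: Spectral, Phase-Synchrony and Classification Analysis of Meditation EEG and Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting mindfulness-meditation and control recordings of
    multichannel EEG and respiration. Implements Bartlett (averaged-periodogram)
    power spectral density estimation with Blackman-Harris tapering and two-way
    within-subject ANOVA of band-by-region power, the Stockwell transform for
    respiration time-frequency analysis, phase-lock-value (PLV) synchrony with a
    phase-randomized-surrogate significance threshold, and an RBF-SVM
    meditation-state classifier built on S-transform features downsampled by a
    kernel canonical correlation (KCCA) dependency criterion. A seeded synthetic
    session generator with injectable ocular and high-voltage artifacts makes the
    whole pipeline testable without access to recordings, and a minimal EDF/BDF
    codec handles on-disk sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
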