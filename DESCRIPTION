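Package: flightcallr
Title: Acoustic Similarity Analysis of Songbird Nocturnal Flight Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for testing whether short songbird
    vocalizations (nocturnal flight calls) encode individual identity and
    sex. Provides a seeded generator of synthetic American Redstart-style
    flight-call populations with controllable individual, sex, age and
    call-variant structure; WAV and Raven-style selection-table input and
    output; short-time Fourier spectrograms; a registry of 95
    energy-distribution (Acoustat-style) acoustic measurements with
    correlation-based feature pruning; unsupervised random-forest proximity
    as a pairwise call-similarity matrix with within- versus
    between-individual tests; permutational MANOVA (pseudo-F, R-squared,
    permutation p-values) for single, crossed and individual-nested
    designs; and principal coordinates / non-metric multidimensional
    scaling ordination with group confidence ellipses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    vegan,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
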