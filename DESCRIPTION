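Package: imbef
Title: Sleep Stage Classification from Single-Channel EEG with Model-Based
    Essence Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic sleep stage classification from single-channel EEG
    using improved model-based essence features (IMBEFs): wavelet-packet
    locality energies fused with the parameters of dual innovation-form
    state-space models estimated from the two first-level wavelet sub-bands
    of each epoch, classified with bagged decision trees under 10-fold
    cross-validation.  Includes EDF/EDF+ and hypnogram readers, R&K and
    AASM label schemes, a periodized wavelet-packet transform, an
    output-only subspace system-identification routine, grid-search model
    selection, confusion-matrix metrics (accuracy, Cohen's kappa,
    per-class sensitivity), and a synthetic stage-labelled EEG generator
    for fully offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    class,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
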