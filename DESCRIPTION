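Package: specdecode
Title: Oscillatory-Aperiodic Decomposition and Decoding of EEG Attention
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates oscillatory and aperiodic components of epoched EEG
    with irregular-resampling auto-spectral analysis (IRASA), and quantifies
    visuospatial-attention encoding through pseudo-trial multivariate
    decoding (stratified five-fold linear support vector machines scored by
    balanced accuracy) and a hemispheric alpha lateralisation modulation
    index, including a rhythmic-versus-arrhythmic TMS contrast over a right
    posterior electrode cluster.  Ships the accompanying statistical layer
    (one-sample t-tests, Benjamini-Hochberg false discovery rate control,
    Holm correction, one-way repeated-measures ANOVA, partial Spearman
    correlation) and a synthetic EEG generator with known aperiodic
    exponent, offset, and condition-lateralised alpha modulation, so the
    full pipeline can be validated end-to-end against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
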