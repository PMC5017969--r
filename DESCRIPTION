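Package: semgvowel
Title: Silent-Speech Vowel Recognition from Facial Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for recognising silently articulated
    vowels from single-channel facial surface electromyography (sEMG).
    Provides zero-phase preprocessing (DC removal, 0.15-450 Hz band-pass,
    50 Hz IIR notch), a 57-feature multi-domain extractor (time, entropy,
    frequency and Symlet-4 wavelet descriptors), minimum-Redundancy
    Maximum-Relevance (mRMR) feature ranking, a one-hidden-layer tanh
    network sized by the 2n+1 rule and trained by scaled conjugate
    gradient with early stopping, and stratified k-fold evaluation with
    confusion matrices and one-vs-rest ROC curves.  A class-conditioned
    synthetic sEMG generator makes every stage testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
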