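Package: adspeech
Title: Speech-Based Alzheimer's Disease Assessment from Syllable Token Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing Alzheimer's disease (AD) likelihood from
    one-minute spoken responses to neuropsychological tests. Speech is
    represented as a Feature Sequence: an ordered sequence of syllable
    tokens plus a silence token drawn from a closed vocabulary. The package
    implements the full pipeline: a log mel-filterbank front-end with
    per-utterance cepstral mean and variance normalization; a convolutional
    recurrent transcriber trained with connectionist temporal classification
    (CTC) that converts audio into Feature Sequences using a greedy decode
    in which long runs of CTC blanks become silence tokens; a bidirectional
    gated recurrent unit (GRU) classifier mapping a Feature Sequence to an
    AD-likelihood score in [0, 1]; sequence-quality metrics (edit distance,
    token error rate, length difference); and a repeated cross-validation
    protocol reporting AUROC, sensitivity and specificity. Synthetic
    two-class cohorts, toy audio with known alignments, and a
    transcription-error corruption model allow the whole pipeline to be
    exercised at desk scale. All recurrent networks, CTC, and convolutions
    are implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
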