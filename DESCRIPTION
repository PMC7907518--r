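Package: demscreen
Title: Acoustic Screening of Alzheimer's Dementia from Spontaneous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two acoustic systems for speech-based screening of Alzheimer's
    dementia (AD). The first slices recordings into 0.96 s patches, maps each
    patch to a 96 x 64 log-mel spectrogram and a 128-D embedding, PCA-whitens
    the embeddings, classifies patches with one of five classifiers (RBF SVM,
    linear SVM, perceptron, SGD-trained MLP, cosine 1-NN) and aggregates
    patch decisions per subject by majority vote. The second, DemCNN, is a
    raw-waveform classifier: anti-aliased decimation by factors (4, 4, 2)
    followed by a six-block one-dimensional convolutional network trained in
    two steps (batch size 32 then 2) with a learning-rate range test and
    automated rate selection. Includes a seeded generator of two-class
    speech-like corpora whose classes differ in pause statistics, syllable
    rate and fundamental-frequency variability, plus speaker-disjoint
    evaluation with precision/recall/F1/accuracy reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
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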