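Package: cxrgen
Title: Encoder-Decoder Report Generation for Chest Radiographs with Additive Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates free-text radiology findings from chest X-ray images
    with a convolutional encoder, additive (Bahdanau) attention over spatial
    image locations, and an LSTM language-model decoder trained by teacher
    forcing under a negative log-likelihood objective with the Adam
    optimiser. Includes report preprocessing and vocabulary construction,
    greedy and beam-search decoding with per-token attention maps, BLEU-1..4
    evaluation with brevity penalty, and a deterministic synthetic
    image/report corpus generator so the full pipeline trains and validates
    without external data. All network computation (forward pass,
    backpropagation through time, Adam) is implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
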