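# cxrgen

Automatic generation of free-text radiology findings from chest X-ray
images, for researchers who study image-to-report models and need a
compact, fully inspectable reference implementation that runs on a
desktop CPU. The package implements the classic injection-style
encoder–decoder captioner with soft visual attention — and, because no
deep-learning framework is involved, every equation (forward pass,
backpropagation through time, Adam) is plain R matrix code that can be
read, tested and instrumented directly.

## The model

An image *I* is mapped by a convolutional encoder to

* a pooled global descriptor, injected once into the decoder at
  *t* = −1 ("tell the LSTM what is in the radiograph"), and
* *n* spatial location features *h₁ … hₙ* from the last convolutional
  block, used by attention.

A report *S = (S₀ … S_N)* bounded by `startseq`/`endseq` sentinels is
modelled autoregressively. At each step the previous decoder output
*m*<sub>t−1</sub> queries additive (Bahdanau) attention:

    e_jt = v' tanh(U h_j + W m_{t-1})         (energies)
    α_t  = softmax(e_t),  Σ_j α_jt = 1        (weights)
    C_t  = Σ_j α_jt h_j                       (context vector)

The word embedding of *S*<sub>t</sub> concatenated with *C*<sub>t</sub>
feeds an LSTM with sigmoid input/forget/output gates,

    i, f, o = σ(W·x_t + W·m_{t-1} + b)
    c_t = f ⊙ c_{t-1} + i ⊙ tanh(W_cx x_t + W_cm m_{t-1} + b_c)
    m_t = o ⊙ c_t,

and an affine vocabulary head with softmax yields
*p*<sub>t+1</sub>(·). Training is teacher-forced under the summed
negative log-likelihood L(I, S) = −Σ log p_t(S_t) (sparse categorical
cross-entropy), minimised with Adam (learning rate 0.001, dropout 0.5
on the encoder penultimate vector and the embeddings); the checkpoint
kept is the one with minimum validation loss. Decoding is greedy
argmax sampling or beam search; reports are scored with BLEU-1..4
(clipped n-gram precisions, cumulative weights, brevity penalty
min(1, e^{1−r/c})).

A deterministic synthetic corpus generator (`synth_spec()`,
`generate_synth_corpus()`) produces thorax-like PNG images whose
bright "abnormality" blobs map one-to-one onto templated findings
sentences, so the entire pipeline trains, validates and is tested
without any external dataset.

## Worked example

```r
library(cxrgen)

manifest <- generate_synth_corpus(synth_spec(), "synthetic_cxr")
fit <- cxrgen(manifest, control = train_control(batch_size = 16, seed = 1))
fit
#> Chest-X-ray report generator (toy backbone, with attention)
#>   vocabulary: 20 tokens;  l_max: 24
#>   records: 160 train / 40 held out
#>   selected epoch 29 of 30 (min validation loss 0.1191)

preds <- predict(fit)         # greedy reports for the held-out images
head(preds$report, 3)
#> [1] "there is an opacity in the left lung the heart is enlarged"
#> [2] "the heart is enlarged there is a pleural effusion on the right"
#> [3] "there is an opacity in the left lung"

evaluate_reports(fit)$corpus  # corpus BLEU against the reference findings
#> BLEU-1 1.0000  BLEU-2 1.0000  BLEU-3 1.0000  BLEU-4 1.0000  (BP 1.0000)

label_normality(preds$report[1])
#> [1] "abnormal"
```

The fitted object supports `print`, `summary`, `coef`, `plot`
(training/validation curves), `predict` (greedy or `method = "beam"`,
optionally with per-token attention weights), `simulate` (stochastic
decoding), `logLik`, and `save_checkpoint()`/`load_checkpoint()`.
`predict(..., attention = TRUE)` plus `attention_heatmap()` renders
the per-token attention maps as PNG overlays.

A command-line interface with `synth`, `preprocess`, `train`,
`generate` and `evaluate` subcommands is available through
`cxrgen_cli()` and the installed wrapper script
(`system.file("cli", "cxrgen", package = "cxrgen")`).

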