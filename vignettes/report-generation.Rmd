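---
title: "Generating chest-X-ray reports with attention: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating chest-X-ray reports with attention: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Radiology findings are short free-text descriptions of what a reader
sees on an image. `cxrgen` treats report writing as conditional
sequence generation: given an image $I$, maximise the likelihood of
the token sequence $S = (S_0, \dots, S_N)$, factorised by the chain
rule into per-step conditionals $p(S_t \mid I, S_0, \dots, S_{t-1})$.
The conditionals are realised by an LSTM whose input at each step is
the embedding of the previous token concatenated with an attention
context vector over spatial image features. The model family is the
injection-style captioner: the image enters the recurrence exactly
once, as the step input at $t = -1$, rather than at every step —
repeated injection makes the decoder re-confront pixel noise at every
step and encourages overfitting.

Everything is implemented in base R matrix code, including
backpropagation through time and Adam. That is a deliberate design
decision, not a limitation: at the corpus sizes this package targets,
a framework-free implementation is fast enough, has no binary
dependencies, and every gradient can be (and is) checked against
finite differences in the test suite.

## Pipeline components

**Text preprocessing.** Findings are lowercased; every token that is
not purely ASCII-alphabetic is removed (digits, punctuation,
non-ASCII letters all act as separators). Long findings are packed
greedily, left to right, into chunks of at most `max_words` (default
22) words: whole sentences are kept together whenever the next
sentence still fits, and a single overlong sentence is split at
exactly `max_words`. Each chunk becomes its own training record, so
one image may carry several reference reports. The concatenation of
chunk tokens always equals the filtered token stream — a property the
tests enforce. The chunking rule itself is our choice; only the
existence of chunking, the filters and the 22-word bound are given by
the problem statement.

**Vocabulary.** Token ids are assigned deterministically: `startseq`
and `endseq` take ids 1 and 2, then corpus words in descending
frequency with lexicographic tie-break; id 0 is padding and never a
word. Determinism matters because vocabularies must be reproducible
across runs without storing extra state.

**Encoder.** Two backbone shapes are provided. `"vgg16"` follows the
classic 16-layer stack (3×3 convolutions in five blocks of widths
64-64/128-128/256×3/512×3/512×3, each block followed by 2×2 max
pooling, then two 4096-wide fully connected ReLU layers); its
penultimate 1×4096 vector is the global image descriptor. `"toy"` is
a reduced stack (default channels 8-16-16, one pooling per block)
sized for 64×64 synthetic images. In both cases the spatial map of
the last convolutional block provides the $n$ attention locations —
the single pooled vector alone cannot support attention, so the
per-location features come from the last feature map, linearly
projected to width `d_attn`; the pooled descriptor passes through
dropout, a dense layer and ReLU to width `d_out` and is used only for
the $t=-1$ injection.

The backbone weights are drawn once from a seeded initialisation (or
loaded from a file) and then frozen; only the projection head,
embeddings, attention and LSTM are trained. A frozen random
convolutional stack is a perfectly serviceable feature extractor at
this scale — it preserves blob identity and location — and it keeps
the training loop focused on the sequence model, which is the part
under study. Fine-tuning the convolutional stack is out of scope.

**Attention.** Additive scoring
$e_{jt} = v^\top \tanh(U h_j + W m_{t-1})$ with the *previous* decoder
output as query. Normalisation is softmax — the canonical map
satisfying the non-negativity and sum-to-one constraints the context
vector requires. One head by default. The context vector is always a
convex combination of location features, which gives a cheap
invariant (coordinate-wise bounds) that the tests exploit.

**Decoder.** Standard gate equations with logistic gates and tanh
candidate. The emitted output is $m_t = o_t \odot c_t$, *without* a
tanh on the cell: the source formulation writes the output gate
multiplying the cell directly, and we follow it; `output_tanh = TRUE`
restores the textbook variant. The vocabulary head is affine with
bias. Hidden width defaults to 64 in the desk-scale profile (the
width is otherwise a free parameter; nothing pins it).

**Training.** Teacher forcing: the ground-truth token at $t$ is the
input when predicting $t+1$. The loss is the per-sequence sum of
$-\log p_t(S_t)$ over non-pad positions, averaged over the batch;
a probability of exactly zero for the correct token is clamped at
$10^{-12}$ and reported. Optimisation is Adam with
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ at learning
rate 0.001, batch 16 in the desk-scale profile (the reference
configuration uses 64; at 160 training records that would give 3
updates per epoch, so the desk profile uses 16), gradient clipping at
global norm 5 (protection for small-batch spikes; disabled by setting
it large). Dropout 0.5 is applied to the encoder penultimate vector
and to the word embeddings, with inverted scaling so evaluation mode
needs no correction. Initialisation is Glorot-uniform for matrices,
zeros for biases, all seeded. The returned checkpoint is always the
epoch with minimum validation loss — the generic form of picking the
epoch where held-out loss bottoms out before overfitting. By default
the 20% test split doubles as the validation set for the training
curves; pass an explicit `split` for a stricter three-way protocol.

**Inference.** Greedy decoding takes the argmax at each step (ties
broken by lowest token id, for determinism) until `endseq` or
`max_len - 1` words, flagging truncation. Beam search ranks
hypotheses by raw summed log-probability — no length normalisation by
default, because the selection rule should match greedy at $k=1$
exactly; a `length_norm` flag exists. Completed hypotheses retire
into a candidate pool rather than blocking a beam slot. A
`stochastic` flag replaces the argmax with a draw from $p_t$, for
readings of "sampling" that mean ancestral sampling.

**Evaluation.** BLEU-1..4 with cumulative weights, including the
printed-precision form $(0.33, 0.33, 0.33, 0)$ for BLEU-3 (switch
`bleu_weights(exact_thirds = TRUE)` for exact thirds). No smoothing
by default — a zero precision at any weighted order gives score 0,
the plain definition — with an optional `smooth_eps` because short
clinical sentences frequently contain no matching 4-gram at all. The
brevity penalty uses the closest-length reference, ties to the
shorter. Corpus-level scores pool clipped counts and lengths before
computing precisions. Sentence normality labelling follows the
keyword rule: a sentence containing any of "no", "normal", "clear",
"stable" is labelled normal; the keyword set is configurable.

## The synthetic corpus

`synth_spec()` defines the bundled study conditions: 200 images of
64×64 pixels, a dark background with a brighter thorax ellipse, and
three findings (left-lung opacity, enlarged cardiac silhouette, right
pleural effusion), each present independently with probability 0.35,
each adding a bright Gaussian blob at a finding-specific location
(±2 px seeded jitter) and one templated sentence to the report in
fixed inventory order; images with no finding read "the lungs are
clear". Pixel noise is Gaussian with SD 0.05 against blob contrast
~0.6, so the signal-to-noise ratio is high by construction and a
small frozen encoder can separate the classes. The full vocabulary is
20 tokens and the longest report is 20 words, within the 22-word
chunking bound.

What the generator emulates: the manifest layout (PNG images +
JSON-lines image/findings pairs), a deterministic image-to-report
mapping, compositional reports (multiple findings concatenated), and
a meaningful normal/abnormal split. What it does not emulate:
anatomical realism, inter-reader variability, long multi-sentence
findings with rare vocabulary, laterality confusions, or label noise.
Passing the end-to-end tests therefore demonstrates that the
implementation can learn a clean compositional image-conditioned
language task — it says nothing about clinical performance on real
radiographs, which requires external corpora and far larger encoders.

## Problem sizes and numerical choices

The test suite and the acceptance script train on the default
200-image corpus (160/40 split) for up to 30 epochs with the
desk-scale profile (toy backbone, pooled width 48, location features
32, hidden width 64) — about half a minute per run on one CPU. The
ablation comparison trains the attention and no-attention variants
over three seeds and compares median held-out corpus BLEU-1. Oracle
tolerances: 1e-10 against the scalar LSTM reference, 1e-6 for
attention and BLEU, 1e-8 for loss sums and log-probability
self-consistency; analytic gradients against central finite
differences at 1e-4 relative. Degenerate inputs are handled
explicitly: empty energy vectors, empty candidates (all BLEU scores
0 with a warning), empty reports (encoded as start/end/padding),
out-of-vocabulary tokens (error naming the token), non-finite states
and images (errors), training divergence (abort naming the batch).

## Known limitations

* The backbone is frozen; no gradients flow into convolutions.
* Single-layer unidirectional LSTM only; recurrent alternatives and
  stacked variants are out of scope.
* Beam search has no coverage or repetition penalty; degenerate loops
  are possible with untrained models (bounded by `max_len`).
* The 4096-wide `"vgg16"` head is memory-hungry (~1 GB of weights)
  and is intended for shape-contract validation and pluggable
  pretrained weights, not desk-scale training.
* BLEU is the only metric; clinical-efficacy metrics are not
  implemented.
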