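---
title: "Methods: a dual-pathway denoising autoencoder for protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-pathway denoising autoencoder for protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`protdae` implements a protein language model that maintains two
representations in parallel and lets them exchange information in a
controlled, cheap way:

* a **local** representation — one `d_local`-vector per sequence position
  (default 128 channels), carrying per-residue information;
* a **global** representation — one `d_global`-vector per protein (default
  512 features), carrying whole-protein information such as functional
  annotations.

Token sequences enter the local pathway through an embedding layer; a binary
annotation vector (one bit per term of a fixed annotation vocabulary,
default size 8943) enters the global pathway through a fully connected
layer. Six transformer-like blocks then transform both. Within a block:

1. **Local convolutions.** Two 1D convolutions run in parallel on the same
   input — a *narrow* one (kernel 9, dilation 1, receptive field 9) and a
   *wide* one (kernel 9, dilation 5, receptive field 41) — their outputs are
   concatenated and reduced back to `d_local` channels by a position-wise
   dense layer. Because the branches are parallel, each block widens the
   receptive field by 40 positions, so the six-block stack sees
   `1 + 6 * 40 = 241` input positions. (A sequential arrangement would give
   289; the parallel topology is what reproduces the printed total.)
2. **Broadcast.** A dense layer maps the global vector to `d_local` features
   that are added at every position — the only route from global to local.
3. **Global attention.** Each of 4 heads computes a single query
   `q = tanh(Wq x)` from the global state, keys `k_i = tanh(Wk s_i)` and
   values `v_i = GELU(Wv s_i)` from the positions, scores
   `<q, k_i> / sqrt(d_key)`, softmax weights `z`, and output
   `y = sum_i z_i v_i`. One query per protein means O(L) cost, not the
   O(L^2) of self-attention, and the whole attention state is a simple
   `heads x L` map that can be displayed directly. Head outputs are
   concatenated (4 x 128 = 512) and added to the global stream — the only
   route from local to global.
4. **Global dense pair.** Two fully connected `d_global` layers.

Every sub-transformation is wrapped in a residual connection followed by
layer normalization (post-norm), and all hidden activations are GELU. No
positional embedding exists anywhere, and no layer's parameter shape depends
on L, so one set of weights applies to any sequence length. At the default
configuration the model holds 16,079,625 trainable parameters (~16M).

Two output heads serve pretraining: a per-position 26-way softmax over the
token vocabulary and a per-annotation sigmoid.

### Design choices that the textual description leaves open

The block description above fixes several details that a prose account of
the architecture cannot pin down; they are deliberate package choices:

* **Sub-layer order** — local convolutions, broadcast, attention, global
  dense, with post-norm after each. The information flow (broadcast feeds
  the local stream before attention reads it) is the only ordering
  constraint we rely on.
* **Score scaling** by `sqrt(d_key)`, the convention the attention design
  is derived from.
* **No biases** in `Wq`/`Wk`/`Wv`, matching the formulas; all dense and
  convolutional layers elsewhere carry biases.
* **No output projection** after head concatenation: the concatenated width
  already equals `d_global`, and the attention layer names only three
  matrices, so the output enters the global stream by residual addition.
* **Convolutions** use same-padding and stride 1; PAD positions are not
  masked anywhere — the PAD embedding has to be learned as uninformative.
* **Initialization** is fan-in-scaled gaussian with a user-supplied seed;
  output-head weights are untied from the input embedding.

## Tokenization and encoding

26 tokens: the 20 standard amino acids (alphabetical), selenocysteine `U`,
unknown `X`, `OTHER` for any remaining letter (B, Z, J, ...), and `START`,
`END`, `PAD`. Sequences that fit the chosen encoding length are wrapped in
`START`/`END` and PAD-filled. Longer sequences contribute a random
contiguous window that omits at least one terminus; a window anchored at the
first residue keeps `START`, one anchored at the last keeps `END`, interior
windows keep neither. Sampling is uniform over all admissible windows, which
is the least-assuming reading of "leave out at least one end" and gives
every offset equal coverage (verified by a chi-square uniformity test in the
suite). When the sequence exceeds the length by exactly one, the only
admissible windows are the two marker-anchored ones; truncation without
windowing is never used.

## The denoising objective

Pretraining corrupts inputs and asks the model to reconstruct clean
targets:

* each token is replaced with probability 0.05 by a uniform draw from all
  26 tokens (the draw may reproduce the original, so the observed change
  rate is `0.05 * 25/26`); special-token positions are eligible, since the
  scheme is defined over tokens, not residues (a switch can exempt them);
* each present annotation is dropped with probability 0.25 and each absent
  one switched on with probability 1e-4;
* with probability 0.5 the whole annotation input is zeroed *before*
  per-bit corruption, forcing annotation prediction from sequence alone.
  Targets are never blanked, and the annotation loss is always computed
  against the true annotations.

The loss is the per-example *sum* (not mean) of the categorical
cross-entropy over all positions plus the binary cross-entropy over all
annotations, averaged over the minibatch. Summing over PAD positions
matches the literal objective; a `mask_pad` switch excludes them for users
who prefer it. Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logs,
which floors the achievable loss at roughly `1e-7` per clipped term.

Encoding length is switched periodically during training (default cycle
128/512/1024). The switch is step-counted rather than wall-clock timed so
that runs are exactly reproducible. The optimizer is Adam (default learning
rate 2e-4); the original training procedure does not document its
optimizer, so it is exposed entirely through configuration.

## Fine-tuning protocol

A task head (dropout, default rate 0.5, then one dense layer) reads the
final local states for per-residue tasks or the final global state for
per-protein tasks, with sigmoid / softmax / identity activation for binary
/ categorical / continuous labels. The annotation input is the all-zero
vector in every fine-tuning forward pass. Three stages:

1. head-only, backbone frozen, up to 40 epochs;
2. everything unfrozen, up to 40 epochs;
3. one final epoch at a doubled encoding length, so the model adapts to
   longer inputs than it was tuned on.

Stages 1–2 use learning-rate-on-plateau (factor 0.25 after 2 stalled
epochs) and early stopping (4 stalled epochs), each stage with independent
counters, and restore the best-validation weights at stage end. These
plateau constants are package defaults — the protocol description leaves
them open. Labels at residues cropped out by windowing are excluded from
loss and metrics, an unavoidable consequence of fixed-length encoding.

Evaluation supports accuracy, Spearman rank correlation and rank-based AUC;
local tasks pool residue-level predictions over labeled positions only.

## Synthetic corpora and what they show

`generate_corpus()` plants fixed residue motifs (default three 8-mers) into
i.i.d. uniform background sequence (lengths 30–80) and attaches an
annotation id exactly when its motif was inserted, so sequence and
annotation carry mutual information that denoising training can exploit.
`generate_toy_task()` builds three supervised tasks mirroring the
benchmark taxonomy: per-residue labeling of an N-terminal motif
(signal-peptide-like, offsets 0–5, motif covering ~20% of residues so that
the majority-class floor of ~0.8 stays well below a learned model),
which-motif classification, and a noisy linear function of motif copy
count. A string-matching oracle achieves ~1.0 on each task, confirming the
planted signal is recoverable; a majority-class baseline gives the floor.

These corpora are deliberately simple: uniform background, no homology
structure, no compositional biases, no length/annotation correlations.
Tests passing on them demonstrate that the architecture, objective and
protocol can extract planted sequence signal end to end — not that the
model reaches any particular quality on natural proteins.

## Problem sizes and numerical choices

The network, backpropagation and Adam are implemented directly over base R
matrix operations (convolutions as kernel-tap shifted matrix products,
attention as segment-wise softmax over stacked batches); the backward pass
is verified against central finite differences at every tensor type. The
learning checks in the test suite use a reduced configuration
(`d_local = 16`, `d_global = 32`, 2 blocks, 2 heads, kernel 5, dilations
1/3): 2,000 pretraining steps on a 5,000-record corpus, a 500-record
per-residue task, and ten seeded repeats of a 100-record classification
comparison between pretrained and from-scratch initialization. Structural
checks (parameter count, receptive fields, attention map shape, length
scaling) always run at the full default configuration. Checkpoints are
single RDS files carrying the configuration and every named tensor;
loading verifies the stored configuration against an expected one and
fails loudly on any mismatch.

Known limitations: no GPU path, so full-scale pretraining is out of reach;
annotation vocabularies are unordered label sets (no ontology semantics);
pairwise outputs (e.g. residue–residue contacts) do not fit the model's
output structure and are not provided.
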