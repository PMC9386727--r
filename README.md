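# protdae

Dual-pathway denoising autoencoders for protein sequences and whole-protein
annotations, in pure R.

`protdae` is for computational biologists who want a protein language model
that is small enough to train and dissect on a CPU, yet structurally
faithful to the modern pretraining recipe: it maintains a per-residue
(**local**, `B x L x d_local`) and a per-protein (**global**,
`B x d_global`) representation in parallel, coupled only by broadcast
layers (global → local) and **linear-complexity global attention**
(local → global). Within each of six transformer-like blocks the local
pathway runs parallel narrow (receptive field 9) and wide (dilated,
receptive field 41) convolutions — 241 positions after six blocks — and the
global pathway runs paired dense layers; residual connections and layer
normalization wrap every sub-transformation. One attention head computes

    q = tanh(Wq x),  k_i = tanh(Wk s_i),  v_i = GELU(Wv s_i)
    z  = softmax( <q, k_i> / sqrt(d_key) ),   y = sum_i z_i v_i

— one query per *protein*, so attention costs O(L) rather than O(L²), and
the whole attention state is a `heads x L` map you can print. No positional
embeddings exist, so a single set of weights applies to any sequence
length. The default configuration (d_local 128, d_global 512, 6 blocks, 4
heads, 8943 annotation outputs) has ~16M trainable parameters.

Pretraining is a denoising task: tokens are randomly replaced (5%),
annotations dropped (25%) / falsely added (0.01%) / wholly blanked (50% of
proteins), and the model recovers the clean sequence and annotation set
under a summed categorical + binary cross-entropy. Fine-tuning follows a
staged protocol — frozen-backbone head training, full unfreezing, one final
epoch at doubled encoding length — with the annotation input forced to
zero. A synthetic-corpus generator plants recoverable motifs so the whole
pipeline is testable without any external database. The network,
backpropagation and Adam optimizer are implemented directly over base R
matrix operations and verified against finite differences.

## Worked example

Pretrain a reduced model on a synthetic motif corpus, fine-tune it on the
per-residue motif-labeling task, and inspect its attention:

```r
library(protdae)

cfg <- model_config(d_local = 16, d_global = 32, n_blocks = 2, n_heads = 2,
                    d_key = 8, conv_kernel = 5, wide_dilation = 3,
                    n_annotations = 3)
model <- build_model(cfg, seed = 1)
model
#> Dual-pathway protein model
#> Model config: d_local 16 | d_global 32 | blocks 2 | heads 2 (d_key 8, d_value 16) | kernel 5 dil 1/3 | vocab 26 | annotations 3
#>   trainable parameters: 15,549

corpus <- generate_corpus(corpus_spec(n_records = 2000, seed = 7))
fit <- pretrain(model, corpus, steps = 600,
                schedule = length_schedule(c(48, 64), 150),
                avocab = annotation_vocabulary(ids = sprintf("GO:%07d", 1:3)),
                batch_size = 16, seed = 7)
fit
#> Pretraining run: 600 steps, batch 16
#>   loss 183.206 -> 43.988 (sequence 180.389 -> 42.707)

task <- generate_toy_task("local_binary", n = 300, seed = 11)
tuned <- finetune(fit$model, task, seed = 11,
                  schedule = finetune_schedule(frozen_epochs_max = 10,
                                               unfrozen_epochs_max = 10))
tuned
#> Fine-tuning: local binary task | 21 epochs across 3 stages
#>   best validation loss 0.0122

evaluate_task(tuned$model, task, "accuracy")
#> [1] 0.9994444
evaluate_task(tuned$model, task, "auc")
#> [1] 0.9999981

extract_attention(tuned$model, task$test$sequence[1])
#> Attention map: 4 heads x 42 positions
```

Reading the numbers: the pretraining loss is the per-example *summed*
cross-entropy (sequence + annotations), so at encoding length 64 the final
sequence loss of 42.7 is ~0.67 nats/position, far below the ln 26 ≈ 3.26
uniform baseline — the model has learned the corpus statistics. After the
staged protocol the per-residue classifier labels planted-motif residues
with 99.9% accuracy against a ~80% majority-class floor. The attention map
has one simplex row per (block, head); row sums are exactly 1, and
`attention_diff()` of before/after-fine-tuning maps gives rows summing
to 0.

A command-line shell over the same functions ships in
`inst/scripts/protdae` (`pretrain`, `finetune`, `evaluate`,
`inspect-attention`, `make-fixtures`).

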