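Package: protdae
Title: Dual-Pathway Denoising Autoencoders for Protein Sequences and Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A length-agnostic protein language model combining a per-residue
    (local) convolutional pathway with a per-protein (global) pathway coupled
    by broadcast layers and linear-complexity global attention. Implements the
    corruption-based denoising pretraining task over sequences and whole-protein
    annotation sets, the staged fine-tuning protocol (frozen head, full
    unfreeze, one longer-length epoch), task heads for local/global binary,
    categorical and continuous labels, attention-map extraction and diffing,
    and a synthetic corpus generator with planted motifs for end-to-end testing
    without external databases. The network, backpropagation and optimizer are
    implemented directly over base R matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
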