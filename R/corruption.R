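#' Corruption configuration for denoising pretraining
#'
#' The pretraining task corrupts each input and asks the model to recover the
#' clean data. Defaults follow the published scheme: each sequence token is
#' kept with 95% probability or replaced by a uniformly drawn token (which may
#' redraw the original); present annotations are dropped with 25%
#' probability; each absent annotation is switched on with probability 0.01%;
#' and for half of the proteins the whole annotation input is blanked to
#' force annotation prediction from sequence alone.
#'
#' @param p_token_replace Per-position replacement probability (default 0.05).
#' @param p_annot_remove Per-set-bit removal probability (default 0.25).
#' @param p_annot_add Per-unset-bit false-addition probability (default 1e-4).
#' @param p_annot_blank Per-protein probability of zeroing the entire
#'   annotation input (default 0.5).
#' @param corrupt_specials Whether START/END/PAD positions are eligible for
#'   replacement corruption (default TRUE: replacement applies to every
#'   token).
#' @return Object of class `corruption_config`.
#' @export
corruption_config <- function(p_token_replace = 0.05, p_annot_remove = 0.25,
                              p_annot_add = 1e-4, p_annot_blank = 0.5,
                              corrupt_specials = TRUE) {
  p <- c(p_token_replace, p_annot_remove, p_annot_add, p_annot_blank)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all corruption probabilities must lie in [0, 1]")
  }
  structure(list(p_token_replace = p_token_replace,
                 p_annot_remove = p_annot_remove,
                 p_annot_add = p_annot_add,
                 p_annot_blank = p_annot_blank,
                 corrupt_specials = isTRUE(corrupt_specials)),
            class = "corruption_config")
}

#' @export
print.corruption_config <- function(x, ...) {
  cat("Corruption: token replace", x$p_token_replace,
      "| annot remove", x$p_annot_remove,
      "| annot add", x$p_annot_add,
      "| annot blank", x$p_annot_blank, "\n")
  invisible(x)
}

#' Corrupt a token sequence by random replacement
#'
#' Each position is independently kept with probability
#' `1 - p_token_replace`, otherwise replaced by a token drawn uniformly over
#' the whole 26-symbol vocabulary (specials included; the draw may reproduce
#' the original token). With `corrupt_specials = FALSE` in the config,
#' START/END/PAD positions are left untouched.
#'
#' @param token_ids Integer vector of 0-based token ids.
#' @param cfg A [corruption_config()].
#' @param vocab Token vocabulary.
#' @return Integer vector of the same length.
#' @export
corrupt_tokens <- function(token_ids, cfg = corruption_config(),
                           vocab = token_vocabulary()) {
  n <- length(token_ids)
  if (n == 0L) return(token_ids)
  if (any(token_ids < 0L | token_ids >= length(vocab$symbols))) {
    stop("token ids out of vocabulary range")
  }
  hit <- stats::runif(n) < cfg$p_token_replace
  if (!cfg$corrupt_specials) {
    specials <- c(.tok_id(vocab, "START"), .tok_id(vocab, "END"),
                  .tok_id(vocab, "PAD"))
    hit <- hit & !(token_ids %in% specials)
  }
  out <- token_ids
  k <- sum(hit)
  if (k > 0L) out[hit] <- sample.int(length(vocab$symbols), k, replace = TRUE) - 1L
  out
}

#' Corrupt an annotation vector
#'
#' With probability `p_annot_blank` the whole vector is zeroed (and no
#' per-bit sampling happens). Otherwise each set bit survives with
#' probability `1 - p_annot_remove` and each unset bit flips on with
#' probability `p_annot_add`.
#'
#' @param bits Integer 0/1 vector.
#' @param cfg A [corruption_config()].
#' @return Integer 0/1 vector of the same length; attribute `"blanked"`
#'   records whether the blanking branch fired.
#' @export
corrupt_annotations <- function(bits, cfg = corruption_config()) {
  if (any(!bits %in% c(0L, 1L))) stop("annotation vector must be binary")
  if (stats::runif(1L) < cfg$p_annot_blank) {
    out <- integer(length(bits))
    attr(out, "blanked") <- TRUE
    return(out)
  }
  out <- as.integer(bits)
  on <- which(bits == 1L)
  off <- which(bits == 0L)
  if (length(on)) out[on[stats::runif(length(on)) < cfg$p_annot_remove]] <- 0L
  if (length(off)) out[off[stats::runif(length(off)) < cfg$p_annot_add]] <- 1L
  attr(out, "blanked") <- FALSE
  out
}

#' Build one denoising training example
#'
#' Encodes a (sequence, annotation set) record once — so input and target
#' share the same sampled window — then corrupts a copy of each input.
#' Targets are never corrupted and never blanked.
#'
#' @param sequence Residue string.
#' @param annotation_ids Character vector of annotation ids (possibly empty).
#' @param target_len Encoded length.
#' @param cfg A [corruption_config()].
#' @param vocab Token vocabulary.
#' @param avocab Annotation vocabulary.
#' @return List with `input_tokens`, `input_annotations`, `target_tokens`,
#'   `target_annotations`, and the `encoding` (the `encoded_seq`).
#' @export
make_pretraining_example <- function(sequence, annotation_ids, target_len,
                                     cfg = corruption_config(),
                                     vocab = token_vocabulary(),
                                     avocab) {
  enc <- encode_sequence(sequence, target_len, vocab)
  clean_annot <- encode_annotations(annotation_ids, avocab)
  list(input_tokens = corrupt_tokens(enc$token_ids, cfg, vocab),
       input_annotations = corrupt_annotations(clean_annot, cfg),
       target_tokens = enc$token_ids,
       target_annotations = clean_annot,
       encoding = enc)
}
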