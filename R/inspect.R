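#' Extract the global-attention map for one sequence
#'
#' Runs the model forward on a single protein and collects the attention
#' distribution of every head in every block: a matrix with
#' `n_blocks * n_heads` rows (24 at the default configuration; block-major,
#' then head index, labeled `"block.head"`) and one column per encoded
#' position. Each row is a softmax output and sums to 1.
#'
#' @param model A `pdae_model`.
#' @param sequence Residue string.
#' @param target_len Encoded length (default: sequence length plus the two
#'   terminal markers).
#' @param annotations Optional annotation input vector; default all-zero.
#' @return Object of class `attention_map` (numeric matrix, rows named
#'   `block.head`, columns named by token symbol).
#' @export
extract_attention <- function(model, sequence, target_len = NULL,
                              annotations = NULL) {
  stopifnot(inherits(model, "pdae_model"))
  cfg <- model$config
  if (is.null(target_len)) target_len <- nchar(sequence) + 2L
  enc <- encode_sequence(sequence, target_len, window = "start")
  tok <- matrix(enc$token_ids, 1L)
  ann <- if (is.null(annotations)) matrix(0, 1L, cfg$n_annotations)
         else matrix(as.numeric(annotations), 1L, cfg$n_annotations)
  fw <- forward_core(model$params, cfg, tok, ann, keep_attention = TRUE)
  rows <- do.call(rbind, fw$attn) # blocks stacked; B = 1 so rows are heads
  rownames(rows) <- as.vector(vapply(seq_len(cfg$n_blocks), function(b)
    paste0(b, ".", seq_len(cfg$n_heads)), character(cfg$n_heads)))
  colnames(rows) <- decode_tokens(enc$token_ids)
  structure(rows, class = c("attention_map", "matrix"))
}

#' Difference between two attention maps
#'
#' Elementwise `after - before`. Because each head's attention sums to 1 in
#' both maps, every row of the difference sums to 0; the diff shows where a
#' fine-tuned model moved attention.
#'
#' @param before,after `attention_map` objects of identical shape.
#' @return Object of class `attention_diff` (matrix, rows summing to 0).
#' @export
attention_diff <- function(before, after) {
  if (!identical(dim(before), dim(after)))
    stop("attention maps have different shapes: ",
         paste(dim(before), collapse = "x"), " vs ",
         paste(dim(after), collapse = "x"))
  structure(unclass(after) - unclass(before),
            class = c("attention_diff", "matrix"))
}

#' @export
print.attention_map <- function(x, ...) {
  cat("Attention map:", nrow(x), "heads x", ncol(x), "positions\n")
  invisible(x)
}

#' @export
print.attention_diff <- function(x, ...) {
  cat("Attention difference:", nrow(x), "heads x", ncol(x),
      "positions (rows sum to 0)\n")
  invisible(x)
}

#' @export
plot.attention_map <- function(x, main = "Global attention", ...) {
  graphics::image(t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE],
                  axes = FALSE, main = main, ...)
  invisible(x)
}

#' Write an attention map (or diff) as TSV
#'
#' Rows labeled `block.head`, one column per position.
#' @param map An `attention_map` or `attention_diff`.
#' @param path Output path.
#' @export
write_attention_tsv <- function(map, path) {
  utils::write.table(unclass(map), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

## ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the configuration, every named
#' weight tensor and any attached task head. Loading verifies the container
#' format and, when an expected configuration is supplied, every field of it
#' — a mismatch (e.g. a different annotation vocabulary size) fails loudly.
#'
#' @param model A `pdae_model`.
#' @param path Checkpoint file path.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pdae_model"))
  saveRDS(list(format = "pdae-checkpoint-v1",
               config = unclass(model$config),
               params = model$params, head = model$head),
          path)
  invisible(path)
}

#' @param config Optional [model_config()] the checkpoint must match.
#' @return `load_checkpoint` returns the restored `pdae_model`.
#' @rdname checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "pdae-checkpoint-v1"))
    stop("'", path, "' is not a model checkpoint")
  ck <- do.call(model_config, obj$config[setdiff(names(obj$config), "d_value")])
  if (!is.null(config)) {
    stopifnot(inherits(config, "pdae_config"))
    diffs <- names(which(!mapply(identical, unclass(ck), unclass(config))))
    if (length(diffs))
      stop("checkpoint config mismatch in field(s): ",
           paste(diffs, collapse = ", "))
  }
  structure(list(config = ck, params = obj$params, head = obj$head),
            class = "pdae_model")
}
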