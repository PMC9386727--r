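#' Dual denoising loss
#'
#' Per example, the loss is the categorical cross-entropy summed over all
#' sequence positions plus the binary cross-entropy summed over all
#' annotations (sums, not means, following the published objective); the
#' batch loss is the mean over examples. Probabilities are clipped to
#' `[eps, 1 - eps]` before logs.
#'
#' @param outputs List with `token_probs` (array `B x L x vocab`) and
#'   `annotation_probs` (matrix `B x n_annotations`), as returned by
#'   `predict(type = "pretrain")`.
#' @param target_tokens Integer matrix `B x L` of 0-based true token ids.
#' @param target_annotations 0/1 matrix `B x n_annotations`.
#' @param pad_mask Optional logical matrix `B x L`; positions marked TRUE are
#'   excluded from the sequence term. Default `NULL` sums over every
#'   position, PAD included.
#' @param eps Clipping constant (default 1e-7).
#' @return Object of class `loss_breakdown`: list with `seq_loss`,
#'   `annot_loss` and `total = seq_loss + annot_loss` (batch means of the
#'   per-example sums).
#' @examples
#' # uniform predictions: 10 positions + 100 absent annotations at 0.5
#' tp <- array(1 / 26, c(1, 10, 26))
#' ap <- matrix(0.5, 1, 100)
#' pretraining_loss(list(token_probs = tp, annotation_probs = ap),
#'                  matrix(0L, 1, 10), matrix(0L, 1, 100))$total
#' # 10 * log(26) + 100 * log(2)
#' @export
pretraining_loss <- function(outputs, target_tokens, target_annotations,
                             pad_mask = NULL, eps = 1e-7) {
  tp <- outputs$token_probs
  ap <- outputs$annotation_probs
  if (length(dim(tp)) != 3L) stop("token_probs must be a B x L x vocab array")
  B <- dim(tp)[1L]; L <- dim(tp)[2L]; V <- dim(tp)[3L]
  target_tokens <- matrix(as.integer(target_tokens), B, L)
  if (!is.matrix(ap)) ap <- matrix(ap, B)
  if (nrow(ap) != B || nrow(target_annotations) != B ||
      ncol(ap) != ncol(target_annotations)) {
    stop("annotation shapes do not match")
  }
  if (any(target_tokens < 0L | target_tokens >= V)) stop("target token id out of range")

  # gather p[b, t, true token]
  bt <- cbind(rep(seq_len(B), times = L), rep(seq_len(L), each = B),
              as.vector(target_tokens) + 1L)
  ptrue <- matrix(tp[bt], B, L)
  nll <- -log(pmin(pmax(ptrue, eps), 1 - eps))
  if (!is.null(pad_mask)) nll[pad_mask] <- 0
  seq_loss <- mean(rowSums(nll))

  apc <- pmin(pmax(ap, eps), 1 - eps)
  A <- target_annotations
  bce <- -(A * log(apc) + (1 - A) * log(1 - apc))
  annot_loss <- if (ncol(apc) == 0L) 0 else mean(rowSums(bce))

  structure(list(seq_loss = seq_loss, annot_loss = annot_loss,
                 total = seq_loss + annot_loss),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss %.4f (sequence %.4f + annotation %.4f)\n",
              x$total, x$seq_loss, x$annot_loss))
  invisible(x)
}
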