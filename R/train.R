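# Adam optimizer and the shared forward/backward training steps. Parameters
# and gradients are congruent nested lists of numeric arrays; the optimizer
# walks the tree recursively.

tree_zero <- function(p) {
  if (is.list(p)) return(lapply(p, tree_zero))
  p * 0
}

adam_state <- function(params) list(m = tree_zero(params), v = tree_zero(params), t = 0L)

# one Adam update; returns list(params, state)
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- m2 <- v2 <- vector("list", length(p))
      names(out) <- names(m2) <- names(v2) <- names(p)
      for (i in seq_along(p)) {
        # gradient trees may order siblings differently; match by name
        gi <- if (is.null(names(p))) g[[i]] else g[[names(p)[i]]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        out[[i]] <- r[[1L]]; m2[[i]] <- r[[2L]]; v2[[i]] <- r[[3L]]
      }
      return(list(out, m2, v2))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p - lr * mh / (sqrt(vh) + eps), m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r[[1L]], state = list(m = r[[2L]], v = r[[3L]], t = t))
}

# forward + backward for the denoising objective. tok_* are B x L 0-based
# matrices, ann_* B x n_annotations. Returns loss breakdown and the full
# gradient tree (backbone + output heads).
pretrain_grads <- function(params, cfg, tok_in, ann_in, tok_tgt, ann_tgt,
                           pad_mask = NULL, eps = 1e-7) {
  fw <- forward_core(params, cfg, tok_in, ann_in, keep_cache = TRUE)
  B <- fw$B; L <- fw$L
  logits <- add_bias(fw$local %*% params$seq_out_W, params$seq_out_b)
  P <- row_softmax(logits)
  tgtv <- as.integer(t(tok_tgt))
  gather <- cbind(seq_len(B * L), tgtv + 1L)
  nll <- -log(pmax(P[gather], eps))
  maskv <- if (is.null(pad_mask)) rep(FALSE, B * L) else as.logical(t(pad_mask))
  nll[maskv] <- 0
  seq_loss <- sum(nll) / B

  dlogits <- P
  dlogits[gather] <- dlogits[gather] - 1
  if (any(maskv)) dlogits[maskv, ] <- 0
  dlogits <- dlogits / B

  alog <- add_bias(fw$global %*% params$annot_out_W, params$annot_out_b)
  pa <- pmin(pmax(sigmoid(alog), eps), 1 - eps)
  A <- ann_tgt
  annot_loss <- if (ncol(pa) == 0L) 0 else
    sum(-(A * log(pa) + (1 - A) * log(1 - pa))) / B
  dalog <- (sigmoid(alog) - A) / B

  g <- backward_core(params, cfg, fw,
                     dS = dlogits %*% t(params$seq_out_W),
                     dX = dalog %*% t(params$annot_out_W))
  g$seq_out_W <- crossprod(fw$local, dlogits)
  g$seq_out_b <- colSums(dlogits)
  g$annot_out_W <- crossprod(fw$global, dalog)
  g$annot_out_b <- colSums(dalog)

  list(loss = structure(list(seq_loss = seq_loss, annot_loss = annot_loss,
                             total = seq_loss + annot_loss),
                        class = "loss_breakdown"),
       grads = g)
}
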