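#' Fine-tuning schedule
#'
#' The staged protocol: (1) freeze every pretrained weight and train only
#' the newly added head for up to `frozen_epochs_max` epochs; (2) unfreeze
#' everything for up to `unfrozen_epochs_max` epochs; (3) one final epoch at
#' a larger encoding length. Stages 1-2 reduce the learning rate on a
#' validation-loss plateau and stop early, each with its own counters.
#'
#' @param frozen_epochs_max,unfrozen_epochs_max Epoch caps (default 40).
#' @param final_long_epoch Run stage 3 (default TRUE).
#' @param lr_factor,lr_patience Plateau reduction: multiply the rate by
#'   `lr_factor` after `lr_patience` epochs without validation improvement.
#' @param early_stopping_patience Epochs without improvement before a stage
#'   stops.
#' @param dropout Dropout rate applied to the head input during training
#'   (default 0.5).
#' @return Object of class `finetune_schedule`.
#' @export
finetune_schedule <- function(frozen_epochs_max = 40L, unfrozen_epochs_max = 40L,
                              final_long_epoch = TRUE, lr_factor = 0.25,
                              lr_patience = 2L, early_stopping_patience = 4L,
                              dropout = 0.5) {
  if (frozen_epochs_max < 1L || unfrozen_epochs_max < 1L)
    stop("epoch caps must be positive")
  structure(list(frozen_epochs_max = as.integer(frozen_epochs_max),
                 unfrozen_epochs_max = as.integer(unfrozen_epochs_max),
                 final_long_epoch = isTRUE(final_long_epoch),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 dropout = dropout),
            class = "finetune_schedule")
}

#' Attach a task head to a model
#'
#' Adds a dropout + fully connected output layer on the final hidden states:
#' local tasks read the per-residue states (`d_local` in), global tasks the
#' per-protein state (`d_global` in). Activation follows the label type —
#' sigmoid for binary, softmax for categorical, none for continuous.
#'
#' @param model A `pdae_model`.
#' @param task A `pdae_task` (or a list with `resolution`, `label_type`,
#'   `k`).
#' @param dropout Training-time dropout on the head input (default 0.5).
#' @param seed Optional seed for head initialization.
#' @return The model with `$head` set.
#' @export
attach_head <- function(model, task, dropout = 0.5, seed = NULL) {
  stopifnot(inherits(model, "pdae_model"))
  if (!task$resolution %in% c("local", "global") ||
      !task$label_type %in% c("binary", "categorical", "continuous")) {
    stop("unsupported head: resolution must be local/global and label type ",
         "binary/categorical/continuous")
  }
  if (task$resolution == "local" && task$label_type == "continuous")
    stop("unsupported head: local continuous labels are not implemented")
  if (!is.null(seed)) set.seed(seed)
  din <- if (task$resolution == "local") model$config$d_local else model$config$d_global
  dout <- switch(task$label_type, binary = 1L, continuous = 1L,
                 categorical = as.integer(task$k))
  model$head <- list(W = .winit(din, dout, fan_in = din), b = numeric(dout),
                     resolution = task$resolution, label_type = task$label_type,
                     k = task$k, dropout = dropout)
  model
}

# head forward on final states; returns activations and (training) caches
head_forward <- function(head, fw, cfg, training = FALSE) {
  H <- if (head$resolution == "local") fw$local else fw$global
  mask <- NULL
  if (training && head$dropout > 0) {
    mask <- matrix(stats::rbinom(length(H), 1L, 1 - head$dropout) /
                     (1 - head$dropout), nrow(H))
    H <- H * mask
  }
  logits <- add_bias(H %*% head$W, head$b)
  out <- switch(head$label_type,
                binary = sigmoid(logits),
                categorical = row_softmax(logits),
                continuous = logits)
  if (head$resolution == "local" && ncol(out) == 1L) {
    # reshape stacked rows back to B x L; multi-column (categorical) output
    # stays stacked example-major, one row per position
    out <- matrix(as.vector(out), fw$B, fw$L, byrow = TRUE)
  }
  list(out = out, logits = logits, H = H, mask = mask)
}

## ---- label encoding against a fixed-length encoding -------------------------

# Build per-batch target structures. For local tasks returns a B x L matrix
# of labels with NA at positions without a usable label (specials, PAD,
# residues cropped out by windowing).
encode_task_batch <- function(df, task, target_len, vocab, window = "random") {
  encs <- lapply(df$sequence, encode_sequence, target_len = target_len,
                 vocab = vocab, window = window)
  tok <- do.call(rbind, lapply(encs, `[[`, "token_ids"))
  B <- nrow(tok); L <- ncol(tok)
  if (task$resolution == "global") {
    y <- if (task$label_type == "categorical") as.integer(df$label)
         else as.numeric(df$label)
    return(list(tok = tok, y = y, mask = NULL))
  }
  lab <- matrix(NA_real_, B, L)
  for (i in seq_len(B)) {
    e <- encs[[i]]
    lv <- as.numeric(strsplit(df$label[i], "")[[1L]])
    if (length(lv) != nchar(df$sequence[i]))
      stop("local label string length mismatch for record ", df$id[i])
    res <- (e$window_offset + 1L):(e$window_offset + e$n_residues)
    pos <- seq_along(res) + as.integer(e$has_start)
    lab[i, pos] <- lv[res]
  }
  list(tok = tok, y = lab, mask = NULL)
}

# loss + gradient at the head for one batch; y per encode_task_batch
head_loss_grads <- function(head, fw, cfg, y, training = TRUE, eps = 1e-7) {
  hf <- head_forward(head, fw, cfg, training = training)
  B <- fw$B
  logits <- hf$logits
  if (head$resolution == "local") {
    yv <- as.vector(t(y)) # stacked example-major
    use <- which(!is.na(yv))
    n_use <- length(use)
    if (head$label_type == "binary") {
      p <- pmin(pmax(sigmoid(logits[, 1L]), eps), 1 - eps)
      loss <- -sum(yv[use] * log(p[use]) + (1 - yv[use]) * log(1 - p[use])) / n_use
      dlog <- matrix(0, length(p), 1L)
      dlog[use, 1L] <- (sigmoid(logits[use, 1L]) - yv[use]) / n_use
    } else { # categorical per position
      P <- row_softmax(logits)
      gather <- cbind(use, as.integer(yv[use]))
      loss <- -sum(log(pmax(P[gather], eps))) / n_use
      dlog <- matrix(0, nrow(P), ncol(P))
      dlog[use, ] <- P[use, , drop = FALSE]
      dlog[gather] <- dlog[gather] - 1
      dlog <- dlog / n_use
    }
  } else if (head$label_type == "categorical") {
    P <- row_softmax(logits)
    gather <- cbind(seq_len(B), as.integer(y))
    loss <- -mean(log(pmax(P[gather], eps)))
    dlog <- P
    dlog[gather] <- dlog[gather] - 1
    dlog <- dlog / B
  } else if (head$label_type == "binary") {
    p <- pmin(pmax(sigmoid(logits[, 1L]), eps), 1 - eps)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dlog <- matrix((sigmoid(logits[, 1L]) - y) / B, ncol = 1L)
  } else { # continuous: mean squared error
    loss <- mean((logits[, 1L] - y)^2)
    dlog <- matrix(2 * (logits[, 1L] - y) / B, ncol = 1L)
  }
  dH <- dlog %*% t(head$W)
  if (!is.null(hf$mask)) dH <- dH * hf$mask
  list(loss = loss,
       gW = crossprod(hf$H, dlog), gb = colSums(dlog),
       dH = dH)
}

# forward states for a token batch with an enforced all-zero annotation input
states_zero_annotation <- function(params, cfg, tok, keep_cache = FALSE) {
  ann <- matrix(0, nrow(tok), cfg$n_annotations)
  stopifnot(all(ann == 0)) # fine-tuning contract: no annotation information
  forward_core(params, cfg, tok, ann, keep_cache = keep_cache)
}

## ---- the staged protocol ----------------------------------------------------

#' Fine-tune a model on a supervised task
#'
#' Runs the three-stage protocol on a task: head-only training with the
#' backbone frozen, full unfreezing, then one epoch at a larger encoding
#' length. The annotation input is the all-zero vector in every forward
#' pass. Validation loss drives learning-rate reduction and early stopping
#' in stages 1-2 (independently); the best-validation weights are restored
#' at the end of each stage.
#'
#' @param model A `pdae_model` (pretrained or fresh); a head is attached if
#'   absent.
#' @param task A `pdae_task` with non-empty train and validation splits.
#' @param schedule A [finetune_schedule()].
#' @param encode_len Encoding length for stages 1-2; default the smallest
#'   power of two covering the longest training sequence plus the two
#'   terminal markers. Stage 3 doubles it.
#' @param batch_size Minibatch size (default 16).
#' @param lr_frozen,lr_unfrozen Adam learning rates for stages 1/2 (stage 3
#'   reuses `lr_unfrozen`).
#' @param seed Optional seed.
#' @param verbose Print per-epoch validation loss.
#' @param stages Which protocol stages to run (default all of `1:3`);
#'   running a prefix is useful for diagnostics, e.g. `stages = 1` to
#'   inspect the frozen-backbone state.
#' @return Object of class `pdae_finetune`: list with `model`, `history`
#'   (stage, epoch, length, train_loss, valid_loss, lr) and `task` metadata.
#' @export
finetune <- function(model, task, schedule = finetune_schedule(),
                     encode_len = NULL, batch_size = 16L,
                     lr_frozen = 1e-2, lr_unfrozen = 1e-3,
                     seed = NULL, verbose = FALSE, stages = 1:3) {
  stopifnot(inherits(model, "pdae_model"), inherits(task, "pdae_task"))
  if (nrow(task$valid) == 0L) stop("validation split must be non-empty")
  if (nrow(task$train) == 0L) stop("training split must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model$head)) model <- attach_head(model, task, schedule$dropout)
  model$head$dropout <- schedule$dropout
  cfg <- model$config
  vocab <- token_vocabulary()
  if (is.null(encode_len)) {
    need <- max(nchar(task$train$sequence)) + 2L
    encode_len <- 2L^ceiling(log2(max(need, 16L)))
  }

  hist <- list()
  run_stage <- function(stage, max_epochs, lr0, frozen, length_use) {
    params <- model$params
    head <- model$head
    opt_b <- if (!frozen) adam_state(params)
    opt_h <- adam_state(head[c("W", "b")])
    lr <- lr0
    best <- Inf; best_params <- params; best_head <- head
    wait_lr <- 0L; wait_stop <- 0L
    n_tr <- nrow(task$train)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      tl <- 0; nb <- 0L
      for (start in seq(1L, n_tr, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n_tr)]
        bt <- encode_task_batch(task$train[rows, , drop = FALSE], task,
                                length_use, vocab)
        fw <- states_zero_annotation(params, cfg, bt$tok, keep_cache = !frozen)
        hl <- head_loss_grads(head, fw, cfg, bt$y, training = TRUE)
        if (!is.finite(hl$loss)) stop("non-finite fine-tuning loss")
        uh <- adam_step(head[c("W", "b")], list(W = hl$gW, b = hl$gb), opt_h, lr)
        head$W <- uh$params$W; head$b <- uh$params$b; opt_h <- uh$state
        if (!frozen) {
          zS <- if (head$resolution == "local") hl$dH else
            matrix(0, fw$B * fw$L, cfg$d_local)
          zX <- if (head$resolution == "global") hl$dH else
            matrix(0, fw$B, cfg$d_global)
          g <- backward_core(params, cfg, fw, dS = zS, dX = zX)
          g$seq_out_W <- params$seq_out_W * 0; g$seq_out_b <- params$seq_out_b * 0
          g$annot_out_W <- params$annot_out_W * 0
          g$annot_out_b <- params$annot_out_b * 0
          ub <- adam_step(params, g, opt_b, lr)
          params <- ub$params; opt_b <- ub$state
        }
        tl <- tl + hl$loss; nb <- nb + 1L
      }
      # validation loss (no dropout, deterministic windows)
      bv <- encode_task_batch(task$valid, task, length_use, vocab,
                              window = "start")
      fwv <- states_zero_annotation(params, cfg, bv$tok)
      vl <- head_loss_grads(head, fwv, cfg, bv$y, training = FALSE)$loss
      hist[[length(hist) + 1L]] <<- data.frame(stage = stage, epoch = epoch,
                                               length = length_use,
                                               train_loss = tl / nb,
                                               valid_loss = vl, lr = lr)
      if (verbose) message(sprintf("stage %d epoch %d valid %.4f lr %.2g",
                                   stage, epoch, vl, lr))
      if (vl < best - 1e-6) {
        best <- vl; best_params <- params; best_head <- head
        wait_lr <- 0L; wait_stop <- 0L
      } else {
        wait_lr <- wait_lr + 1L; wait_stop <- wait_stop + 1L
        if (wait_lr >= schedule$lr_patience) {
          lr <- lr * schedule$lr_factor; wait_lr <- 0L
        }
        if (wait_stop >= schedule$early_stopping_patience) break
      }
    }
    model$params <<- best_params
    model$head <<- best_head
  }

  if (1L %in% stages)
    run_stage(1L, schedule$frozen_epochs_max, lr_frozen, frozen = TRUE,
              length_use = encode_len)
  if (2L %in% stages)
    run_stage(2L, schedule$unfrozen_epochs_max, lr_unfrozen, frozen = FALSE,
              length_use = encode_len)
  if (3L %in% stages && schedule$final_long_epoch) {
    run_stage(3L, 1L, lr_unfrozen, frozen = FALSE,
              length_use = 2L * encode_len)
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 task = list(resolution = task$resolution,
                             label_type = task$label_type, k = task$k),
                 encode_len = encode_len),
            class = "pdae_finetune")
}

#' @export
print.pdae_finetune <- function(x, ...) {
  h <- x$history
  cat("Fine-tuning:", x$task$resolution, x$task$label_type, "task |",
      nrow(h), "epochs across", length(unique(h$stage)), "stages\n")
  cat(sprintf("  best validation loss %.4f\n", min(h$valid_loss)))
  invisible(x)
}

#' Evaluate a fine-tuned model on a task split
#'
#' Local tasks pool residue-level predictions over every position that
#' carries a label (specials and PAD excluded). Supported metrics: accuracy
#' (binary or categorical labels), Spearman rank correlation (continuous)
#' and area under the ROC curve (binary).
#'
#' @param model A `pdae_model` with a head attached (e.g. from
#'   [finetune()]'s `$model`).
#' @param task A `pdae_task`.
#' @param metric `"accuracy"`, `"spearman"` or `"auc"`.
#' @param split Split to score (default `"test"`).
#' @param encode_len Encoding length (default: longest sequence plus 2).
#' @return Numeric score.
#' @export
evaluate_task <- function(model, task, metric = c("accuracy", "spearman", "auc"),
                          split = "test", encode_len = NULL) {
  metric <- match.arg(metric)
  if (is.null(model$head)) stop("model has no task head")
  df <- task[[split]]
  if (nrow(df) == 0L) stop("split '", split, "' is empty")
  ok <- switch(metric,
               accuracy = model$head$label_type %in% c("binary", "categorical"),
               auc = model$head$label_type == "binary",
               spearman = model$head$label_type == "continuous")
  if (!ok) stop("metric '", metric, "' does not apply to ",
                model$head$label_type, " labels")
  cfg <- model$config
  vocab <- token_vocabulary()
  if (is.null(encode_len)) encode_len <- max(nchar(df$sequence)) + 2L
  bt <- encode_task_batch(df, task, encode_len, vocab, window = "start")
  fw <- states_zero_annotation(model$params, cfg, bt$tok)
  pred <- head_forward(model$head, fw, cfg, training = FALSE)$out
  if (model$head$resolution == "local") {
    if (model$head$label_type == "categorical") {
      yv <- as.vector(t(bt$y)); use <- !is.na(yv)
      p <- max.col(pred)[use]; y <- yv[use]
      return(mean(p == y)) # accuracy is the only admissible metric here
    }
    use <- !is.na(bt$y)
    p <- pred[use]; y <- bt$y[use]
  } else if (model$head$label_type == "categorical") {
    p <- max.col(pred); y <- bt$y
  } else {
    p <- pred[, 1L]; y <- bt$y
  }
  switch(metric,
         accuracy = if (model$head$label_type == "categorical") mean(p == y)
                    else mean((p > 0.5) == (y == 1)),
         spearman = stats::cor(p, y, method = "spearman"),
         auc = auc_rank(p, y))
}

# Wilcoxon rank-based AUC
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with `method = "spearman"`, kept as a
#' named metric for task evaluation.
#' @param x,y Numeric vectors.
#' @export
spearman_rho <- function(x, y) stats::cor(x, y, method = "spearman")
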