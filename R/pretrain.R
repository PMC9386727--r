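#' Encoding-length schedule
#'
#' During pretraining the fixed minibatch length is switched periodically so
#' the model never overfits one length; the published run cycled lengths
#' 128/512/1024 on a wall-clock interval, reproduced here as a deterministic
#' step-count interval.
#'
#' @param lengths Distinct positive encoding lengths (default
#'   `c(128, 512, 1024)`).
#' @param switch_every Steps between switches (default 100).
#' @return Object of class `length_schedule`.
#' @export
length_schedule <- function(lengths = c(128L, 512L, 1024L), switch_every = 100L) {
  lengths <- as.integer(lengths)
  if (any(lengths < 3L) || anyDuplicated(lengths))
    stop("lengths must be distinct integers >= 3")
  switch_every <- as.integer(switch_every)
  if (switch_every < 1L) stop("switch_every must be positive")
  structure(list(lengths = lengths, switch_every = switch_every),
            class = "length_schedule")
}

#' @rdname length_schedule
#' @param schedule A `length_schedule`.
#' @param step 1-based training step.
#' @export
schedule_length <- function(schedule, step) {
  i <- ((step - 1L) %/% schedule$switch_every) %% length(schedule$lengths)
  schedule$lengths[i + 1L]
}

#' Blank annotations of held-out-similar proteins
#'
#' Pretraining must not leak annotation information about proteins similar to
#' benchmark test sets. Given a precomputed exclusion set of protein ids
#' (e.g. from an external 40%-similarity search), their annotation sets are
#' emptied; sequences pass through untouched.
#'
#' @param corpus Corpus data frame (`id`, `sequence`, `annotations` list
#'   column).
#' @param excluded_ids Character vector of protein ids.
#' @return The corpus with matching records' annotation sets emptied.
#' @export
apply_annotation_exclusion <- function(corpus, excluded_ids) {
  hit <- corpus$id %in% excluded_ids
  corpus$annotations[hit] <- list(character(0))
  corpus
}

#' Pretrain a model with the denoising objective
#'
#' Runs minibatch gradient descent (Adam) on the dual corruption task: each
#' step samples records, encodes them at the schedule's current length,
#' corrupts the inputs, and minimizes the summed sequence cross-entropy plus
#' annotation binary cross-entropy against the clean targets. The annotation
#' loss always uses the true annotations, including for records whose input
#' vector was blanked.
#'
#' @param model A `pdae_model`.
#' @param corpus Data frame with columns `id`, `sequence` and `annotations`
#'   (a list column of character vectors), e.g. from [generate_corpus()] or
#'   [read_corpus()].
#' @param steps Number of optimization steps.
#' @param corruption A [corruption_config()].
#' @param schedule A [length_schedule()].
#' @param avocab Annotation vocabulary; default placeholder ids sized to the
#'   model config.
#' @param batch_size Records per step (default 16).
#' @param lr Adam learning rate (default 2e-4).
#' @param mask_pad Exclude PAD positions from the sequence loss (default
#'   FALSE: the loss sums over every position).
#' @param seed Optional seed.
#' @param checkpoint_every,checkpoint_path Write an intermediate checkpoint
#'   every so many steps (optional).
#' @param verbose Print a loss line every `report_every` steps.
#' @param report_every Steps between history rows (default 50).
#' @return Object of class `pdae_pretrain`: list with the trained `model`, a
#'   `history` data frame (step, length, seq_loss, annot_loss, total) and the
#'   settings used.
#' @export
pretrain <- function(model, corpus, steps,
                     corruption = corruption_config(),
                     schedule = length_schedule(),
                     avocab = NULL, batch_size = 16L, lr = 2e-4,
                     mask_pad = FALSE, seed = NULL,
                     checkpoint_every = NULL, checkpoint_path = NULL,
                     verbose = FALSE, report_every = 50L) {
  stopifnot(inherits(model, "pdae_model"), nrow(corpus) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  cfg <- model$config
  if (is.null(avocab)) avocab <- annotation_vocabulary(size = cfg$n_annotations)
  if (avocab$size != cfg$n_annotations)
    stop("annotation vocabulary size does not match the model config")
  params <- model$params
  opt <- adam_state(params)
  hist <- vector("list", 0L)
  vocab <- token_vocabulary()

  for (step in seq_len(steps)) {
    len <- schedule_length(schedule, step)
    pick <- sample.int(nrow(corpus), batch_size, replace = batch_size > nrow(corpus))
    exs <- lapply(pick, function(i) {
      make_pretraining_example(corpus$sequence[[i]], corpus$annotations[[i]],
                               len, corruption, vocab, avocab)
    })
    tok_in <- do.call(rbind, lapply(exs, `[[`, "input_tokens"))
    tok_tgt <- do.call(rbind, lapply(exs, `[[`, "target_tokens"))
    ann_in <- do.call(rbind, lapply(exs, function(e) as.numeric(e$input_annotations)))
    ann_tgt <- do.call(rbind, lapply(exs, function(e) as.numeric(e$target_annotations)))
    pad_mask <- if (mask_pad) {
      pad <- .tok_id(vocab, "PAD")
      matrix(tok_tgt == pad, nrow(tok_tgt))
    }
    sg <- pretrain_grads(params, cfg, tok_in, ann_in, tok_tgt, ann_tgt, pad_mask)
    if (!is.finite(sg$loss$total)) {
      stop("non-finite loss at step ", step, " (length ", len, "): seq=",
           sg$loss$seq_loss, " annot=", sg$loss$annot_loss)
    }
    up <- adam_step(params, sg$grads, opt, lr)
    params <- up$params
    opt <- up$state
    if (step == 1L || step %% report_every == 0L || step == steps) {
      hist[[length(hist) + 1L]] <- data.frame(step = step, length = len,
                                              seq_loss = sg$loss$seq_loss,
                                              annot_loss = sg$loss$annot_loss,
                                              total = sg$loss$total)
      if (verbose) {
        message(sprintf("step %d len %d seq %.3f annot %.3f total %.3f",
                        step, len, sg$loss$seq_loss, sg$loss$annot_loss,
                        sg$loss$total))
      }
    }
    if (!is.null(checkpoint_every) && step %% checkpoint_every == 0L) {
      model$params <- params
      save_checkpoint(model, checkpoint_path)
    }
  }
  model$params <- params
  structure(list(model = model, history = do.call(rbind, hist),
                 settings = list(steps = steps, batch_size = batch_size,
                                 lr = lr, schedule = schedule,
                                 corruption = corruption, mask_pad = mask_pad)),
            class = "pdae_pretrain")
}

#' @export
print.pdae_pretrain <- function(x, ...) {
  h <- x$history
  cat("Pretraining run:", x$settings$steps, "steps, batch",
      x$settings$batch_size, "\n")
  cat(sprintf("  loss %.3f -> %.3f (sequence %.3f -> %.3f)\n",
              h$total[1L], h$total[nrow(h)], h$seq_loss[1L],
              h$seq_loss[nrow(h)]))
  invisible(x)
}

#' @export
plot.pdae_pretrain <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$total, type = "l", xlab = "step", ylab = "loss",
                 main = "Denoising pretraining loss", ...)
  graphics::lines(h$step, h$seq_loss, lty = 2)
  graphics::legend("topright", c("total", "sequence"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Write a loss history as TSV
#' @param fit A `pdae_pretrain` (or `pdae_finetune`) object.
#' @param path Output path.
#' @export
write_loss_history <- function(fit, path) {
  utils::write.table(fit$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
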