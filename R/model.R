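#' Model configuration
#'
#' All architecture hyperparameters. Defaults reproduce the published
#' full-scale model: 128 local channels, 512 global features, six blocks with
#' four attention heads each, key dimension 64, kernel size 9 with dilation 1
#' (narrow branch) and 5 (wide branch), a 26-token vocabulary and 8943
#' annotation outputs. The per-head value dimension is `d_global / n_heads`.
#'
#' @param d_local Channels of the per-residue representation.
#' @param d_global Features of the per-protein representation; must be
#'   divisible by `n_heads`.
#' @param n_blocks Number of transformer-like blocks.
#' @param n_heads Global-attention heads per block.
#' @param d_key Query/key dimension.
#' @param conv_kernel Convolution kernel size (odd).
#' @param narrow_dilation,wide_dilation Dilation rates of the two parallel
#'   convolution branches.
#' @param vocab_size Token vocabulary size (26).
#' @param n_annotations Size of the annotation vocabulary.
#' @return Object of class `pdae_config`.
#' @export
model_config <- function(d_local = 128L, d_global = 512L, n_blocks = 6L,
                         n_heads = 4L, d_key = 64L, conv_kernel = 9L,
                         narrow_dilation = 1L, wide_dilation = 5L,
                         vocab_size = 26L, n_annotations = 8943L) {
  cfg <- list(d_local = as.integer(d_local), d_global = as.integer(d_global),
              n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
              d_key = as.integer(d_key), conv_kernel = as.integer(conv_kernel),
              narrow_dilation = as.integer(narrow_dilation),
              wide_dilation = as.integer(wide_dilation),
              vocab_size = as.integer(vocab_size),
              n_annotations = as.integer(n_annotations))
  bad <- character()
  if (any(vapply(cfg, function(v) is.na(v) || v < 1L, logical(1))))
    bad <- c(bad, "all dimensions must be positive integers")
  if (cfg$d_global %% cfg$n_heads != 0L)
    bad <- c(bad, "d_global must be divisible by n_heads")
  if (cfg$conv_kernel %% 2L != 1L)
    bad <- c(bad, "conv_kernel must be odd")
  if (length(bad)) stop("invalid model config: ", paste(bad, collapse = "; "))
  cfg$d_value <- cfg$d_global %/% cfg$n_heads
  structure(cfg, class = "pdae_config")
}

#' @export
print.pdae_config <- function(x, ...) {
  cat("Model config: d_local", x$d_local, "| d_global", x$d_global,
      "| blocks", x$n_blocks, "| heads", x$n_heads,
      paste0("(d_key ", x$d_key, ", d_value ", x$d_value, ")"),
      "| kernel", x$conv_kernel,
      "dil", paste0(x$narrow_dilation, "/", x$wide_dilation),
      "| vocab", x$vocab_size, "| annotations", x$n_annotations, "\n")
  invisible(x)
}

#' Read / write a model configuration as YAML
#' @param path File path.
#' @rdname config_io
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' @param config A `pdae_config`.
#' @rdname config_io
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[setdiff(names(config), "d_value")], path)
  invisible(path)
}

# fan-in-scaled gaussian init
.winit <- function(..., fan_in) {
  d <- c(...)
  array(stats::rnorm(prod(d), sd = 1 / sqrt(fan_in)), dim = d)
}

init_params <- function(cfg) {
  dl <- cfg$d_local; dg <- cfg$d_global; K <- cfg$conv_kernel
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    heads <- lapply(seq_len(cfg$n_heads), function(h) list(
      Wq = .winit(dg, cfg$d_key, fan_in = dg),
      Wk = .winit(dl, cfg$d_key, fan_in = dl),
      Wv = .winit(dl, cfg$d_value, fan_in = dl)))
    list(conv_n_W = .winit(K, dl, dl, fan_in = K * dl), conv_n_b = numeric(dl),
         conv_w_W = .winit(K, dl, dl, fan_in = K * dl), conv_w_b = numeric(dl),
         conv_fc_W = .winit(2L * dl, dl, fan_in = 2L * dl), conv_fc_b = numeric(dl),
         ln1_g = rep(1, dl), ln1_b = numeric(dl),
         bcast_W = .winit(dg, dl, fan_in = dg), bcast_b = numeric(dl),
         ln2_g = rep(1, dl), ln2_b = numeric(dl),
         heads = heads,
         ln3_g = rep(1, dg), ln3_b = numeric(dg),
         fc1_W = .winit(dg, dg, fan_in = dg), fc1_b = numeric(dg),
         fc2_W = .winit(dg, dg, fan_in = dg), fc2_b = numeric(dg),
         ln4_g = rep(1, dg), ln4_b = numeric(dg))
  })
  list(embed = .winit(cfg$vocab_size, dl, fan_in = dl),
       annot_in_W = .winit(cfg$n_annotations, dg, fan_in = cfg$n_annotations),
       annot_in_b = numeric(dg),
       blocks = blocks,
       seq_out_W = .winit(dl, cfg$vocab_size, fan_in = dl),
       seq_out_b = numeric(cfg$vocab_size),
       annot_out_W = .winit(dg, cfg$n_annotations, fan_in = dg),
       annot_out_b = numeric(cfg$n_annotations))
}

#' Build a dual-pathway model
#'
#' Instantiates embeddings, the annotation input layer, `n_blocks`
#' transformer-like blocks (parallel narrow/wide convolutions, position-wise
#' dense, broadcast, multi-head global attention, global dense pair, each with
#' residual connection and post-layer-norm) and the two pretraining output
#' heads (per-position 26-way softmax; per-annotation sigmoid). Weights are
#' fan-in-scaled gaussian. The same weights apply at any sequence length; no
#' positional embedding exists anywhere.
#'
#' @param config A [model_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return Object of class `pdae_model` with elements `config`, `params`,
#'   and `head` (NULL until [attach_head()]).
#' @examples
#' m <- build_model(model_config(d_local = 8, d_global = 8, n_blocks = 1,
#'                               n_heads = 2, d_key = 4, conv_kernel = 3,
#'                               n_annotations = 5), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pdae_config"))
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = config, params = init_params(config), head = NULL),
            class = "pdae_model")
}

#' Count trainable parameters
#'
#' @param model A `pdae_model` (or a raw parameter list).
#' @return Integer count of trainable scalars, including any attached task
#'   head.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "pdae_model")) {
    c(list(model$params), if (!is.null(model$head)) list(model$head[c("W", "b")]))
  } else list(model)
  count_tree <- function(x) {
    if (is.list(x)) return(sum(vapply(x, count_tree, numeric(1))))
    length(x)
  }
  as.integer(sum(vapply(p, count_tree, numeric(1))))
}

#' Analytic convolutional receptive fields
#'
#' Each convolution layer spans `(kernel - 1) * dilation + 1` input
#' positions. The two branches of a block run in parallel on the same input,
#' so a block widens the receptive field by the larger branch span minus one;
#' the full local pathway reaches
#' `1 + n_blocks * (max_branch_span - 1)` input positions.
#'
#' @param config A [model_config()].
#' @return List with `narrow`, `wide` (single-layer spans) and `total` (full
#'   pathway span after the last block).
#' @examples
#' conv_receptive_field(model_config())  # 9, 41, 241
#' @export
conv_receptive_field <- function(config) {
  stopifnot(inherits(config, "pdae_config"))
  narrow <- (config$conv_kernel - 1L) * config$narrow_dilation + 1L
  wide <- (config$conv_kernel - 1L) * config$wide_dilation + 1L
  list(narrow = narrow, wide = wide,
       total = 1L + config$n_blocks * (max(narrow, wide) - 1L))
}

## ---- forward / backward over the block stack --------------------------------

# tok: B x L integer matrix (0-based ids); ann: B x n_annotations matrix.
# Returns final local (B*L x d_local) and global (B x d_global) states, plus
# caches for backprop (keep_cache) and per-head attention weights
# (keep_attention).
forward_core <- function(params, cfg, tok, ann, keep_cache = FALSE,
                         keep_attention = FALSE) {
  B <- nrow(tok); L <- ncol(tok)
  tokv <- as.integer(t(tok)) # stacked example-major
  if (any(tokv < 0L | tokv >= cfg$vocab_size)) stop("token id out of range")
  if (ncol(ann) != cfg$n_annotations || nrow(ann) != B)
    stop("annotation input must be ", B, " x ", cfg$n_annotations)
  r <- rep(seq_len(B), each = L)
  idx_n <- conv_indices(B, L, cfg$conv_kernel, cfg$narrow_dilation)
  idx_w <- conv_indices(B, L, cfg$conv_kernel, cfg$wide_dilation)

  S <- params$embed[tokv + 1L, , drop = FALSE]
  preX <- add_bias(ann %*% params$annot_in_W, params$annot_in_b)
  X <- gelu(preX)

  caches <- if (keep_cache) vector("list", cfg$n_blocks)
  attn <- if (keep_attention) vector("list", cfg$n_blocks)

  for (b in seq_len(cfg$n_blocks)) {
    p <- params$blocks[[b]]
    cb <- list(S_in = S, X_in = X)

    # local conv sub-block: parallel narrow+wide, concat, position-wise dense
    pre_n <- conv_fwd(S, p$conv_n_W, p$conv_n_b, idx_n)
    pre_w <- conv_fwd(S, p$conv_w_W, p$conv_w_b, idx_w)
    cc <- cbind(gelu(pre_n), gelu(pre_w))
    pre_fc <- add_bias(cc %*% p$conv_fc_W, p$conv_fc_b)
    ln1 <- ln_fwd(S + gelu(pre_fc), p$ln1_g, p$ln1_b)
    S1 <- ln1$y

    # broadcast: global -> every position
    pre_bc <- add_bias(X %*% p$bcast_W, p$bcast_b)
    bc <- gelu(pre_bc)
    ln2 <- ln_fwd(S1 + bc[r, , drop = FALSE], p$ln2_g, p$ln2_b)
    S2 <- ln2$y

    # multi-head global attention: local -> global
    hcaches <- vector("list", cfg$n_heads)
    Y <- matrix(0, B, 0L)
    for (h in seq_len(cfg$n_heads)) {
      hp <- p$heads[[h]]
      hr <- attn_head_fwd(S2, X, hp$Wq, hp$Wk, hp$Wv, L, B, r)
      hcaches[[h]] <- hr
      Y <- cbind(Y, hr$y)
    }
    ln3 <- ln_fwd(X + Y, p$ln3_g, p$ln3_b)
    X1 <- ln3$y

    # global dense pair
    pre1 <- add_bias(X1 %*% p$fc1_W, p$fc1_b)
    u <- gelu(pre1)
    pre2 <- add_bias(u %*% p$fc2_W, p$fc2_b)
    ln4 <- ln_fwd(X1 + gelu(pre2), p$ln4_g, p$ln4_b)

    if (keep_cache) {
      caches[[b]] <- c(cb, list(pre_n = pre_n, pre_w = pre_w, cc = cc,
                                pre_fc = pre_fc, ln1 = ln1, S1 = S1,
                                pre_bc = pre_bc, ln2 = ln2, S2 = S2,
                                hcaches = hcaches, ln3 = ln3, X1 = X1,
                                pre1 = pre1, u = u, pre2 = pre2, ln4 = ln4))
    }
    if (keep_attention) {
      attn[[b]] <- do.call(rbind, lapply(hcaches, function(hc)
        matrix(hc$z, nrow = B, byrow = TRUE))) # (n_heads*B) x L, head-major
    }
    S <- S2
    X <- ln4$y
  }

  list(local = S, global = X, B = B, L = L, tokv = tokv, r = r,
       preX = preX, ann = ann, idx_n = idx_n, idx_w = idx_w,
       caches = caches, attn = attn)
}

# dS, dX: gradients w.r.t. the final local/global states. Returns the full
# gradient tree (same shape as params).
backward_core <- function(params, cfg, fw, dS, dX) {
  B <- fw$B; L <- fw$L; r <- fw$r
  g <- list(blocks = vector("list", cfg$n_blocks))

  for (b in rev(seq_len(cfg$n_blocks))) {
    p <- params$blocks[[b]]
    cb <- fw$caches[[b]]
    gb <- list()

    # global dense pair (X1 -> X_out)
    l4 <- ln_bwd(dX, cb$ln4, p$ln4_g)
    gb$ln4_g <- l4$dg; gb$ln4_b <- l4$db
    dsum <- l4$dx
    dpre2 <- dsum * gelu_grad(cb$pre2)
    gb$fc2_W <- crossprod(cb$u, dpre2); gb$fc2_b <- colSums(dpre2)
    du <- dpre2 %*% t(p$fc2_W)
    dpre1 <- du * gelu_grad(cb$pre1)
    gb$fc1_W <- crossprod(cb$X1, dpre1); gb$fc1_b <- colSums(dpre1)
    dX1 <- dsum + dpre1 %*% t(p$fc1_W)

    # attention (X,S2 -> X1)
    l3 <- ln_bwd(dX1, cb$ln3, p$ln3_g)
    gb$ln3_g <- l3$dg; gb$ln3_b <- l3$db
    dXmid <- l3$dx # grad into X + Y
    dS2 <- matrix(0, B * L, cfg$d_local)
    dXacc <- dXmid
    gb$heads <- vector("list", cfg$n_heads)
    for (h in seq_len(cfg$n_heads)) {
      hp <- p$heads[[h]]
      cols <- ((h - 1L) * cfg$d_value + 1L):(h * cfg$d_value)
      hb <- attn_head_bwd(dXmid[, cols, drop = FALSE], cb$S2, cb$X_in,
                          hp$Wq, hp$Wk, hp$Wv, fw$caches[[b]]$hcaches[[h]],
                          L, B, r)
      dS2 <- dS2 + hb$dS
      dXacc <- dXacc + hb$dX
      gb$heads[[h]] <- list(Wq = hb$dWq, Wk = hb$dWk, Wv = hb$dWv)
    }
    dS2 <- dS2 + dS # residual stream: S2 is also the block's local output

    # broadcast (S1, X -> S2)
    l2 <- ln_bwd(dS2, cb$ln2, p$ln2_g)
    gb$ln2_g <- l2$dg; gb$ln2_b <- l2$db
    dS1 <- l2$dx
    dbc <- rowsum(l2$dx, r) # collapse per-position grads back to the example
    dpre_bc <- dbc * gelu_grad(cb$pre_bc)
    gb$bcast_W <- crossprod(cb$X_in, dpre_bc); gb$bcast_b <- colSums(dpre_bc)
    dXacc <- dXacc + dpre_bc %*% t(p$bcast_W)

    # local conv sub-block (S_in -> S1)
    l1 <- ln_bwd(dS1, cb$ln1, p$ln1_g)
    gb$ln1_g <- l1$dg; gb$ln1_b <- l1$db
    dS_in <- l1$dx
    dpre_fc <- l1$dx * gelu_grad(cb$pre_fc)
    gb$conv_fc_W <- crossprod(cb$cc, dpre_fc); gb$conv_fc_b <- colSums(dpre_fc)
    dcc <- dpre_fc %*% t(p$conv_fc_W)
    dl <- cfg$d_local
    dpre_n <- dcc[, 1:dl, drop = FALSE] * gelu_grad(cb$pre_n)
    dpre_w <- dcc[, (dl + 1L):(2L * dl), drop = FALSE] * gelu_grad(cb$pre_w)
    cn <- conv_bwd(dpre_n, cb$S_in, p$conv_n_W, fw$idx_n)
    cw <- conv_bwd(dpre_w, cb$S_in, p$conv_w_W, fw$idx_w)
    gb$conv_n_W <- cn$dW; gb$conv_n_b <- cn$db
    gb$conv_w_W <- cw$dW; gb$conv_w_b <- cw$db
    dS_in <- dS_in + cn$dX + cw$dX

    g$blocks[[b]] <- gb
    dS <- dS_in
    dX <- dXacc
  }

  # input layers: scatter-add per-position grads into the embedding rows
  tmp <- rowsum(dS, fw$tokv)
  g$embed <- matrix(0, cfg$vocab_size, cfg$d_local)
  g$embed[as.integer(rownames(tmp)) + 1L, ] <- tmp
  dpreX <- dX * gelu_grad(fw$preX)
  g$annot_in_W <- crossprod(fw$ann, dpreX)
  g$annot_in_b <- colSums(dpreX)
  g
}

## ---- user-facing forward ----------------------------------------------------

#' Run the model forward
#'
#' @param object A `pdae_model`.
#' @param sequences Character vector of residue strings, or a pre-encoded
#'   integer matrix `B x L` of 0-based token ids.
#' @param annotations Optional `B x n_annotations` 0/1 matrix; defaults to
#'   the all-zero "no information" input.
#' @param target_len Encoded length when `sequences` are strings (default:
#'   longest sequence plus the two terminal markers).
#' @param type `"pretrain"` for the denoising heads (per-position token
#'   distributions and annotation probabilities), `"head"` for the attached
#'   fine-tuning head, `"states"` for the raw final local/global states.
#' @param ... Unused.
#' @return For `"pretrain"`: list with `token_probs` (array `B x L x 26`,
#'   rows summing to 1) and `annotation_probs` (`B x n_annotations` in
#'   `[0,1]`). For `"head"`: the head output (see [attach_head()]). For
#'   `"states"`: list with `local`, `global`.
#' @export
predict.pdae_model <- function(object, sequences, annotations = NULL,
                               target_len = NULL,
                               type = c("pretrain", "head", "states"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  enc <- encode_batch(sequences, target_len, cfg)
  tok <- enc$tok
  B <- nrow(tok)
  if (is.null(annotations)) {
    annotations <- matrix(0, B, cfg$n_annotations)
  } else {
    annotations <- matrix(as.numeric(annotations), B, cfg$n_annotations)
  }
  fw <- forward_core(object$params, cfg, tok, annotations)
  switch(type,
    pretrain = {
      logits <- add_bias(fw$local %*% object$params$seq_out_W,
                         object$params$seq_out_b)
      probs <- row_softmax(logits)
      alog <- add_bias(fw$global %*% object$params$annot_out_W,
                       object$params$annot_out_b)
      list(token_probs = aperm(array(t(probs), c(cfg$vocab_size, ncol(tok), B)),
                               c(3L, 2L, 1L)),
           annotation_probs = sigmoid(alog),
           encodings = enc$encodings)
    },
    states = list(local = fw$local, global = fw$global, B = B, L = ncol(tok),
                  encodings = enc$encodings),
    head = {
      if (is.null(object$head)) stop("no task head attached; see attach_head()")
      head_forward(object$head, fw, cfg, training = FALSE)$out
    })
}

# encode a batch of strings (deterministic windows) or pass through a matrix
encode_batch <- function(sequences, target_len, cfg) {
  if (is.matrix(sequences)) {
    return(list(tok = sequences, encodings = NULL))
  }
  if (is.null(target_len)) target_len <- max(nchar(sequences)) + 2L
  encs <- lapply(sequences, encode_sequence, target_len = target_len,
                 window = "start")
  list(tok = do.call(rbind, lapply(encs, `[[`, "token_ids")), encodings = encs)
}

row_softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @export
print.pdae_model <- function(x, ...) {
  cfg <- x$config
  cat("Dual-pathway protein model\n")
  print(cfg)
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","),
      if (!is.null(x$head)) "(incl. task head)", "\n")
  if (!is.null(x$head)) {
    cat("  task head:", x$head$resolution, x$head$label_type, "\n")
  }
  invisible(x)
}

#' @export
summary.pdae_model <- function(object, ...) {
  rf <- conv_receptive_field(object$config)
  structure(list(config = object$config,
                 n_parameters = count_parameters(object),
                 receptive_field = rf, head = object$head),
            class = "summary.pdae_model")
}

#' @export
print.summary.pdae_model <- function(x, ...) {
  print(x$config)
  cat("Parameters:", format(x$n_parameters, big.mark = ","), "\n")
  cat("Receptive field: narrow", x$receptive_field$narrow,
      "| wide", x$receptive_field$wide,
      "| full local pathway", x$receptive_field$total, "\n")
  invisible(x)
}

#' @export
coef.pdae_model <- function(object, ...) object$params

#' Measure a receptive field by perturbation
#'
#' Empirical cross-check of [conv_receptive_field()]: feeds a random input,
#' perturbs one central position, and measures the span of output positions
#' that change (dilated kernels touch positions inside the span sparsely, so
#' the span — last affected minus first affected plus one — is the receptive
#' field). For `"full"` the whole local pathway of a built model is probed
#' with the broadcast weights zeroed, cutting the global-to-local coupling so
#' that influence can only travel through the convolutions.
#'
#' @param config A [model_config()]; only kernel/dilation/block structure
#'   matter, so small channel counts probe quickly.
#' @param layer `"narrow"`, `"wide"` (one conv layer) or `"full"` (the whole
#'   local pathway).
#' @param L Probe sequence length (default: comfortably wider than the
#'   analytic field).
#' @param seed RNG seed for the probe weights.
#' @return Integer: number of output positions affected by the perturbation.
#' @export
receptive_field_probe <- function(config, layer = c("narrow", "wide", "full"),
                                  L = NULL, seed = 1L) {
  layer <- match.arg(layer)
  stopifnot(inherits(config, "pdae_config"))
  set.seed(seed)
  rf <- conv_receptive_field(config)
  if (layer %in% c("narrow", "wide")) {
    dil <- if (layer == "narrow") config$narrow_dilation else config$wide_dilation
    if (is.null(L)) L <- 2L * rf[[layer]] + 21L
    d <- 4L
    W <- array(stats::rnorm(config$conv_kernel * d * d), c(config$conv_kernel, d, d))
    X <- matrix(stats::rnorm(L * d), L, d)
    idx <- conv_indices(1L, L, config$conv_kernel, dil)
    base <- conv_fwd(X, W, numeric(d), idx)
    Xp <- X; mid <- (L + 1L) %/% 2L
    Xp[mid, ] <- Xp[mid, ] + 1
    pert <- conv_fwd(Xp, W, numeric(d), idx)
    hit <- which(rowSums(abs(pert - base)) > 0)
    return(max(hit) - min(hit) + 1L) # span, not count: dilated taps leave gaps
  }
  if (is.null(L)) L <- rf$total + 60L
  probe_cfg <- model_config(d_local = 6L, d_global = 8L,
                            n_blocks = config$n_blocks, n_heads = 2L,
                            d_key = 4L, conv_kernel = config$conv_kernel,
                            narrow_dilation = config$narrow_dilation,
                            wide_dilation = config$wide_dilation,
                            vocab_size = config$vocab_size, n_annotations = 4L)
  m <- build_model(probe_cfg)
  for (b in seq_len(probe_cfg$n_blocks)) { # cut global -> local coupling
    m$params$blocks[[b]]$bcast_W[] <- 0
    m$params$blocks[[b]]$bcast_b[] <- 0
  }
  tok <- matrix(sample.int(probe_cfg$vocab_size, L, replace = TRUE) - 1L, 1L)
  ann <- matrix(0, 1L, probe_cfg$n_annotations)
  base <- forward_core(m$params, probe_cfg, tok, ann)$local
  mid <- (L + 1L) %/% 2L
  tokp <- tok
  tokp[1L, mid] <- (tokp[1L, mid] + 1L) %% probe_cfg$vocab_size
  pert <- forward_core(m$params, probe_cfg, tokp, ann)$local
  hit <- which(rowSums(abs(pert - base)) > 0)
  max(hit) - min(hit) + 1L
}
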