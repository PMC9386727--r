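test_that("config validation reports violated invariants", {
  expect_error(model_config(d_global = 100, n_heads = 3), "divisible")
  expect_error(model_config(conv_kernel = 8), "odd")
  expect_error(model_config(n_blocks = 0), "positive")
  cfg <- model_config()
  expect_identical(cfg$d_value, 128L)
  expect_identical(cfg$d_value * cfg$n_heads, cfg$d_global)
})

test_that("global attention matches a brute-force oracle on random instances", {
  set.seed(11)
  worst <- 0
  for (rep in 1:120) {
    L <- sample(1:8, 1); dl <- sample(2:4, 1); dg <- sample(2:5, 1)
    dk <- sample(2:3, 1); dv <- sample(2:3, 1)
    x <- rnorm(dg); s <- matrix(rnorm(L * dl), L)
    Wq <- matrix(rnorm(dg * dk), dg)
    Wk <- matrix(rnorm(dl * dk), dl)
    Wv <- matrix(rnorm(dl * dv), dl)
    got <- global_attention_head(x, s, Wq, Wk, Wv)
    ref <- oracle_attention(x, s, Wq, Wk, Wv)
    expect_equal(sum(got$z), 1, tolerance = 1e-12)
    expect_true(all(got$z >= 0))
    worst <- max(worst, max(abs(got$y - ref$y)), max(abs(got$z - ref$z)))
  }
  expect_lt(worst, 1e-10)
})

test_that("attention limits: singleton and symmetric inputs", {
  set.seed(12)
  Wq <- matrix(rnorm(8), 4); Wk <- matrix(rnorm(6), 3); Wv <- matrix(rnorm(6), 3)
  x <- rnorm(4)
  s1 <- matrix(rnorm(3), 1)
  got <- global_attention_head(x, s1, Wq, Wk, Wv)
  expect_equal(got$z, 1.0)
  pre <- as.numeric(s1 %*% Wv)
  expect_equal(got$y, pre * pnorm(pre), tolerance = 1e-12)
  # identical positions share attention equally
  s7 <- matrix(rep(rnorm(3), each = 7), 7)
  expect_equal(global_attention_head(x, s7, Wq, Wk, Wv)$z, rep(1 / 7, 7),
               tolerance = 1e-12)
  expect_error(global_attention_head(x, matrix(0, 0, 3), Wq, Wk, Wv), "L >= 1")
})

test_that("multi-head attention concatenates heads and ignores position order", {
  set.seed(13)
  heads <- lapply(1:4, function(h) list(Wq = matrix(rnorm(5 * 3), 5),
                                        Wk = matrix(rnorm(4 * 3), 4),
                                        Wv = matrix(rnorm(4 * 2), 4)))
  x <- rnorm(5); s <- matrix(rnorm(9 * 4), 9)
  mh <- multi_head_global_attention(x, s, heads)
  expect_length(mh$y, 4 * 2)
  expect_identical(dim(mh$z), c(4L, 9L))
  # position-blind: permuting rows of s leaves y unchanged
  perm <- sample(9)
  mh2 <- multi_head_global_attention(x, s[perm, ], heads)
  expect_equal(mh2$y, mh$y, tolerance = 1e-12)
  # one head reproduces the single-head computation
  h1 <- global_attention_head(x, s, heads[[1]]$Wq, heads[[1]]$Wk, heads[[1]]$Wv)
  expect_identical(mh$y[1:2], h1$y)
  # default dimensions give a 512-wide concatenation
  cfg <- model_config()
  expect_identical(cfg$n_heads * cfg$d_value, 512L)
})

test_that("block stack preserves shapes across sequence lengths", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  for (L in c(8L, 64L, 300L)) {
    tok <- matrix(sample(0:25, 2 * L, TRUE), 2)
    ann <- matrix(0, 2, cfg$n_annotations)
    fw <- protdae:::forward_core(m$params, cfg, tok, ann)
    expect_identical(dim(fw$local), c(2L * L, cfg$d_local))
    expect_identical(dim(fw$global), c(2L, cfg$d_global))
    expect_true(all(is.finite(fw$local)), all(is.finite(fw$global)))
  }
})

test_that("zeroed coupling isolates the global pathway from sequence content", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 6)
  for (b in seq_len(cfg$n_blocks)) {
    for (h in seq_len(cfg$n_heads)) m$params$blocks[[b]]$heads[[h]]$Wv[] <- 0
  }
  ann <- matrix(rbinom(cfg$n_annotations, 1, 0.5), 1)
  tok1 <- matrix(sample(0:25, 30, TRUE), 1)
  tok2 <- matrix(sample(0:25, 30, TRUE), 1)
  g1 <- protdae:::forward_core(m$params, cfg, tok1, ann)$global
  g2 <- protdae:::forward_core(m$params, cfg, tok2, ann)$global
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("model outputs are valid probability structures at any length", {
  cfg <- toy_config()
  m <- build_model(cfg, seed = 7)
  set.seed(7)
  for (L in c(16L, 128L)) {
    tok <- matrix(sample(0:25, 3 * L, TRUE), 3)
    out <- predict(m, tok)
    expect_identical(dim(out$token_probs), c(3L, L, 26L))
    sums <- apply(out$token_probs, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-5))
    expect_true(all(out$annotation_probs >= 0 & out$annotation_probs <= 1))
  }
})

test_that("default model parameter count rounds to 16 million", {
  m <- build_model(model_config(), seed = 1)
  n <- count_parameters(m)
  expect_identical(round(n / 1e6), 16)
})

test_that("toy parameter count matches a hand-enumerated ledger", {
  cfg <- model_config(d_local = 4, d_global = 8, n_blocks = 1, n_heads = 2,
                      d_key = 3, conv_kernel = 3, n_annotations = 5)
  m <- build_model(cfg, seed = 1)
  dl <- 4; dg <- 8; K <- 3; dv <- dg / 2; dk <- 3; V <- 26; A <- 5
  ledger <- V * dl +                 # embedding
    A * dg + dg +                    # annotation input
    2 * (K * dl * dl + dl) +         # narrow + wide conv
    (2 * dl) * dl + dl +             # position-wise dense
    2 * 2 * dl +                     # ln1, ln2
    dg * dl + dl +                   # broadcast
    2 * (dg * dk + dl * dk + dl * dv) + # two attention heads
    2 * 2 * dg +                     # ln3, ln4
    2 * (dg * dg + dg) +             # global dense pair
    dl * V + V +                     # sequence head
    dg * A + A                       # annotation head
  expect_identical(count_parameters(m), as.integer(ledger))
  # zero blocks degenerate: embedding + annotation I/O + heads only
  cfg0 <- cfg; cfg0$n_blocks <- 0L
  m0 <- build_model(cfg0, seed = 1)
  expect_identical(count_parameters(m0),
                   as.integer(V * dl + A * dg + dg + dl * V + V + dg * A + A))
})

test_that("parameter count is stable across forward passes and rebuilds", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 42)
  m2 <- build_model(cfg, seed = 42)
  expect_identical(m1$params, m2$params)
  n0 <- count_parameters(m1)
  invisible(predict(m1, matrix(sample(0:25, 10, TRUE), 1)))
  expect_identical(count_parameters(m1), n0)
})

test_that("no positional embedding exists in the parameter ledger", {
  m <- build_model(tiny_config(), seed = 1)
  all_names <- function(x, prefix = "") {
    if (!is.list(x)) return(prefix)
    unlist(lapply(seq_along(x), function(i) {
      nm <- if (is.null(names(x)) || names(x)[i] == "") as.character(i)
            else names(x)[i]
      all_names(x[[i]], paste0(prefix, "/", nm))
    }))
  }
  nms <- all_names(m$params)
  expect_false(any(grepl("pos", nms, ignore.case = TRUE)))
  # every tensor is independent of L: no dimension tied to sequence length
  expect_true(length(nms) > 0)
})

test_that("receptive fields: analytic values and perturbation probes agree", {
  cfg <- model_config()
  rf <- conv_receptive_field(cfg)
  expect_identical(rf$narrow, 9L)
  expect_identical(rf$wide, 41L)
  expect_identical(rf$total, 241L)
  expect_identical(receptive_field_probe(cfg, "narrow"), 9L)
  expect_identical(receptive_field_probe(cfg, "wide"), 41L)
  expect_identical(receptive_field_probe(cfg, "full"), 241L)
  # a non-default geometry follows the same law
  cfg2 <- model_config(conv_kernel = 5, wide_dilation = 3, n_blocks = 2)
  rf2 <- conv_receptive_field(cfg2)
  expect_identical(rf2$narrow, 5L)
  expect_identical(rf2$wide, 13L)
  expect_identical(rf2$total, 25L)
  expect_identical(receptive_field_probe(cfg2, "full"), 25L)
})

test_that("attention score work grows linearly in L", {
  # the score computation is one dot product per (position, head): count them
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 3)
  for (L in c(32L, 64L, 128L)) {
    tok <- matrix(sample(0:25, L, TRUE), 1)
    fw <- protdae:::forward_core(m$params, cfg, tok,
                                 matrix(0, 1, cfg$n_annotations),
                                 keep_attention = TRUE)
    n_scores <- sum(vapply(fw$attn, length, numeric(1)))
    expect_identical(n_scores, as.numeric(cfg$n_blocks * cfg$n_heads * L))
  }
})

test_that("backpropagation matches central finite differences", {
  set.seed(77)
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 77)
  B <- 2L; L <- 6L
  tok_in <- matrix(sample(0:25, B * L, TRUE), B, L)
  tok_tgt <- matrix(sample(0:25, B * L, TRUE), B, L)
  ann_in <- matrix(rbinom(B * cfg$n_annotations, 1, 0.4), B)
  ann_tgt <- matrix(rbinom(B * cfg$n_annotations, 1, 0.4), B)
  sg <- protdae:::pretrain_grads(m$params, cfg, tok_in, ann_in, tok_tgt, ann_tgt)
  loss_at <- function(params)
    protdae:::pretrain_grads(params, cfg, tok_in, ann_in, tok_tgt, ann_tgt)$loss$total
  get_leaf <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1L) { tree[[path[[1L]]]] <- val; return(tree) }
    tree[[path[[1L]]]] <- set_leaf(tree[[path[[1L]]]], path[-1L], val)
    tree
  }
  paths <- list(list("annot_in_W"), list("blocks", 1L, "conv_w_W"),
                list("blocks", 1L, "conv_fc_W"), list("blocks", 1L, "bcast_W"),
                list("blocks", 1L, "heads", 2L, "Wk"),
                list("blocks", 1L, "heads", 1L, "Wq"),
                list("blocks", 1L, "heads", 1L, "Wv"),
                list("blocks", 1L, "ln2_g"), list("blocks", 1L, "fc2_W"),
                list("seq_out_W"), list("annot_out_b"))
  h <- 1e-5
  for (pth in paths) {
    leaf <- get_leaf(m$params, pth)
    i <- sample(length(leaf), 1L)
    up <- leaf; up[i] <- up[i] + h
    dn <- leaf; dn[i] <- dn[i] - h
    num <- (loss_at(set_leaf(m$params, pth, up)) -
              loss_at(set_leaf(m$params, pth, dn))) / (2 * h)
    ana <- get_leaf(sg$grads, pth)[i]
    expect_equal(ana, num, tolerance = 1e-5)
  }
})
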