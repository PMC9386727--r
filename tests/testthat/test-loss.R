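test_that("uniform predictions give the closed-form cross-entropy", {
  tp <- array(1 / 26, c(1, 10, 26))
  ap <- matrix(0.5, 1, 100)
  lb <- pretraining_loss(list(token_probs = tp, annotation_probs = ap),
                         matrix(0L, 1, 10), matrix(0L, 1, 100))
  expect_equal(lb$seq_loss, 10 * log(26), tolerance = 1e-9)
  expect_equal(lb$annot_loss, 100 * log(2), tolerance = 1e-9)
  expect_equal(lb$total, 10 * log(26) + 100 * log(2), tolerance = 1e-6)
  expect_equal(lb$total, lb$seq_loss + lb$annot_loss)
})

test_that("near-perfect predictions drive the loss toward zero", {
  tgt <- matrix(c(0L, 3L, 25L), 1)
  tp <- array(1e-9, c(1, 3, 26))
  for (t in 1:3) tp[1, t, tgt[1, t] + 1] <- 1 - 25e-9
  ap <- matrix(c(1 - 1e-9, 1e-9), 1)
  lb <- pretraining_loss(list(token_probs = tp, annotation_probs = ap),
                         tgt, matrix(c(1L, 0L), 1))
  expect_lt(lb$total, 1e-5)
  expect_gte(lb$total, 0)
})

test_that("loss agrees with a scalar-loop oracle on random instances", {
  set.seed(21)
  for (rep in 1:5) {
    B <- sample(1:3, 1); L <- sample(2:6, 1); A <- sample(0:8, 1)
    raw <- array(runif(B * L * 26), c(B, L, 26))
    tp <- raw / rep(apply(raw, c(1, 2), sum), times = 26)
    ap <- matrix(runif(B * A), B, A)
    tgt <- matrix(sample(0:25, B * L, TRUE), B, L)
    ta <- matrix(rbinom(B * A, 1, 0.5), B, A)
    lb <- pretraining_loss(list(token_probs = tp, annotation_probs = ap),
                           tgt, ta)
    # independent element-by-element accumulation
    eps <- 1e-7
    tot_seq <- 0; tot_ann <- 0
    for (b in seq_len(B)) {
      for (t in seq_len(L)) {
        p <- min(max(tp[b, t, tgt[b, t] + 1], eps), 1 - eps)
        tot_seq <- tot_seq - log(p)
      }
      for (j in seq_len(A)) {
        p <- min(max(ap[b, j], eps), 1 - eps)
        tot_ann <- tot_ann - (ta[b, j] * log(p) + (1 - ta[b, j]) * log(1 - p))
      }
    }
    expect_equal(lb$seq_loss, tot_seq / B, tolerance = 1e-8)
    expect_equal(lb$annot_loss, tot_ann / B, tolerance = 1e-8)
  }
})

test_that("per-example loss scales linearly with length for uniform tokens", {
  for (L in c(5L, 50L)) {
    tp <- array(1 / 26, c(2, L, 26))
    lb <- pretraining_loss(list(token_probs = tp,
                                annotation_probs = matrix(0.5, 2, 0)),
                           matrix(0L, 2, L), matrix(0L, 2, 0))
    expect_equal(lb$seq_loss, L * log(26), tolerance = 1e-9)
    expect_identical(lb$annot_loss, 0)
  }
})

test_that("pad masking removes PAD positions from the sequence term", {
  tp <- array(1 / 26, c(1, 6, 26))
  mask <- matrix(c(rep(FALSE, 4), TRUE, TRUE), 1)
  lb <- pretraining_loss(list(token_probs = tp,
                              annotation_probs = matrix(0, 1, 0)),
                         matrix(0L, 1, 6), matrix(0L, 1, 0), pad_mask = mask)
  expect_equal(lb$seq_loss, 4 * log(26), tolerance = 1e-9)
})

test_that("shape mismatches raise explicit errors", {
  tp <- array(1 / 26, c(1, 4, 26))
  expect_error(pretraining_loss(list(token_probs = matrix(1, 2, 2),
                                     annotation_probs = matrix(0.5, 1, 2)),
                                matrix(0L, 1, 4), matrix(0L, 1, 2)),
               "array")
  expect_error(pretraining_loss(list(token_probs = tp,
                                     annotation_probs = matrix(0.5, 1, 3)),
                                matrix(0L, 1, 4), matrix(0L, 1, 2)),
               "shapes")
  expect_error(pretraining_loss(list(token_probs = tp,
                                     annotation_probs = matrix(0.5, 1, 2)),
                                matrix(30L, 1, 4), matrix(0L, 1, 2)),
               "range")
})

test_that("gradient of a confident correct prediction is near zero", {
  # finite-difference probe through the full loss on a tiny model trained to
  # saturation is costly; instead verify the analytic property directly at
  # the softmax/sigmoid gradient used by training
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 8)
  tok <- matrix(sample(0:25, 6, TRUE), 1)
  ann <- matrix(rbinom(cfg$n_annotations, 1, 0.5), 1)
  sg <- protdae:::pretrain_grads(m$params, cfg, tok, ann, tok, ann)
  # push output biases to make the true classes near-certain
  m$params$seq_out_W[] <- 0
  m$params$seq_out_b[] <- -50
  m$params$annot_out_W[] <- 0
  m$params$annot_out_b[] <- ifelse(ann[1, ] == 1, 50, -50)
  for (t in seq_along(tok)) {
    # per-position certainty requires position-dependent logits, so check a
    # single-position batch per target token
    tok1 <- matrix(tok[1, t], 1)
    m2 <- m
    m2$params$seq_out_b[tok[1, t] + 1] <- 50
    sg2 <- protdae:::pretrain_grads(m2$params, cfg, tok1, ann, tok1, ann)
    # the clipping epsilon (1e-7 per clipped probability) floors the loss
    expect_lt(sg2$loss$total, 1e-5)
    expect_lt(max(abs(sg2$grads$seq_out_b)), 1e-8)
    expect_lt(max(abs(sg2$grads$annot_out_b)), 1e-8)
  }
})
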