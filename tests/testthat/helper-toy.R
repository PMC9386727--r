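# Shared fixtures: a reduced configuration that keeps CPU training fast
# while exercising every architectural component (two blocks, two heads,
# both conv branches).

toy_config <- function(n_annotations = 3L) {
  model_config(d_local = 16L, d_global = 32L, n_blocks = 2L, n_heads = 2L,
               d_key = 8L, conv_kernel = 5L, narrow_dilation = 1L,
               wide_dilation = 3L, n_annotations = n_annotations)
}

tiny_config <- function(n_annotations = 5L) {
  model_config(d_local = 6L, d_global = 8L, n_blocks = 1L, n_heads = 2L,
               d_key = 4L, conv_kernel = 3L, narrow_dilation = 1L,
               wide_dilation = 2L, n_annotations = n_annotations)
}

random_residue_string <- function(n) {
  paste(sample(token_vocabulary()$symbols[1:20], n, replace = TRUE),
        collapse = "")
}

# brute-force single-head attention written independently of the package's
# vectorized path: explicit loops over positions and the printed formulas
oracle_attention <- function(x, s, Wq, Wk, Wv) {
  L <- nrow(s); dk <- ncol(Wq); dv <- ncol(Wv)
  q <- tanh(as.numeric(t(Wq) %*% x))
  scores <- numeric(L)
  V <- matrix(0, L, dv)
  for (i in seq_len(L)) {
    ki <- tanh(as.numeric(t(Wk) %*% s[i, ]))
    scores[i] <- sum(q * ki) / sqrt(dk)
    pre <- as.numeric(t(Wv) %*% s[i, ])
    V[i, ] <- pre * pnorm(pre) # GELU
  }
  z <- exp(scores - max(scores))
  z <- z / sum(z)
  y <- numeric(dv)
  for (i in seq_len(L)) y <- y + z[i] * V[i, ]
  list(y = y, z = z)
}
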