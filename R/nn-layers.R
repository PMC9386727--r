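# Low-level differentiable layers. Local (per-residue) states for a batch are
# stored example-major as a (B*L) x d matrix: row (b-1)*L + t is position t of
# example b, so matrix(v, L, B) puts one example per column for segment ops.
# All layers return forward values plus whatever the matching *_bwd needs.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# column-broadcast a bias vector over matrix rows
add_bias <- function(M, b) M + rep(b, each = nrow(M))

## ---- layer normalization (row-wise over features, learned gain/offset) ----

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## ---- 1D convolution as K shifted matmuls -----------------------------------

# index vectors mapping each stacked output row to its input row per kernel
# tap; out-of-sequence taps point at a phantom zero row (B*L + 1).
conv_indices <- function(B, L, K, dilation) {
  half <- (K - 1L) %/% 2L
  zero_row <- B * L + 1L
  base <- rep((seq_len(B) - 1L) * L, each = L) # example offset per stacked row
  t_in_ex <- rep(seq_len(L), times = B)
  lapply(seq_len(K), function(k) {
    src <- t_in_ex + (k - 1L - half) * dilation
    out <- base + src
    out[src < 1L | src > L] <- zero_row
    out
  })
}

# W: array K x d_in x d_out; b: length d_out
conv_fwd <- function(X, W, b, idx) {
  Xp <- rbind(X, 0)
  Y <- matrix(rep(b, each = nrow(X)), nrow(X))
  for (k in seq_along(idx)) Y <- Y + Xp[idx[[k]], , drop = FALSE] %*% W[k, , ]
  Y
}

conv_bwd <- function(dY, X, W, idx) {
  Xp <- rbind(X, 0)
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  n <- nrow(X)
  for (k in seq_along(idx)) {
    v <- idx[[k]]
    dW[k, , ] <- crossprod(Xp[v, , drop = FALSE], dY)
    keep <- v <= n
    if (any(keep)) {
      src <- dY[keep, , drop = FALSE] %*% t(W[k, , ])
      rows <- v[keep] # injective within one tap
      dX[rows, ] <- dX[rows, ] + src
    }
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

## ---- segment softmax over stacked scores ------------------------------------

seg_softmax <- function(scores, L, B) {
  m <- matrix(scores, L, B)
  m <- exp(sweep(m, 2L, apply(m, 2L, max)))
  as.vector(sweep(m, 2L, colSums(m), "/"))
}

seg_sums <- function(v, L, B) colSums(matrix(v, L, B))

## ---- global attention (one head, batched) -----------------------------------

# S: (B*L) x d_local, X: B x d_global. r = rep(1:B, each = L).
attn_head_fwd <- function(S, X, Wq, Wk, Wv, L, B, r) {
  dk <- ncol(Wq)
  Q <- tanh(X %*% Wq)
  preK <- S %*% Wk; Kt <- tanh(preK)
  preV <- S %*% Wv; V <- gelu(preV)
  sc <- rowSums(Kt * Q[r, , drop = FALSE]) / sqrt(dk)
  z <- seg_softmax(sc, L, B)
  y <- rowsum(z * V, r)
  list(y = y, z = z, Q = Q, Kt = Kt, preV = preV, V = V)
}

attn_head_bwd <- function(dy, S, X, Wq, Wk, Wv, cache, L, B, r) {
  dk <- ncol(Wq)
  z <- cache$z; Q <- cache$Q; Kt <- cache$Kt; V <- cache$V
  dyr <- dy[r, , drop = FALSE]
  dV <- z * dyr
  dz <- rowSums(V * dyr)
  ds <- z * (dz - seg_sums(z * dz, L, B)[r])
  dsc <- ds / sqrt(dk)
  dKt <- dsc * Q[r, , drop = FALSE]
  dQ <- rowsum(dsc * Kt, r)
  dpreK <- dKt * (1 - Kt * Kt)
  dpreQ <- dQ * (1 - Q * Q)
  dpreV <- dV * gelu_grad(cache$preV)
  list(dS = dpreK %*% t(Wk) + dpreV %*% t(Wv),
       dX = dpreQ %*% t(Wq),
       dWq = crossprod(X, dpreQ),
       dWk = crossprod(S, dpreK),
       dWv = crossprod(S, dpreV))
}

#' Single-head global attention
#'
#' Computes the linear-complexity attention used to pool per-residue states
#' into the per-protein pathway: a single global query `q = tanh(Wq x)`
#' attends over per-position keys `k_i = tanh(Wk s_i)`; scores `<q, k_i>` are
#' scaled by `sqrt(d_key)` and softmaxed into weights `z` (non-negative,
#' summing to 1), and the output is `y = sum_i z_i * GELU(Wv s_i)`. Cost is
#' O(L), not O(L^2): there is one query per protein, not one per position.
#'
#' @param x Numeric vector, the global state (length `d_global`).
#' @param s Numeric matrix `L x d_local` of per-position states (L >= 1).
#' @param Wq `d_global x d_key` query projection.
#' @param Wk `d_local x d_key` key projection.
#' @param Wv `d_local x d_value` value projection.
#' @return List with `y` (length `d_value`) and `z` (length L, sums to 1).
#' @export
global_attention_head <- function(x, s, Wq, Wk, Wv) {
  if (!is.matrix(s) || nrow(s) == 0L) stop("'s' must be a matrix with L >= 1 rows")
  stopifnot(length(x) == nrow(Wq), ncol(s) == nrow(Wk), ncol(s) == nrow(Wv),
            ncol(Wq) == ncol(Wk))
  res <- attn_head_fwd(s, matrix(x, 1L), Wq, Wk, Wv,
                       L = nrow(s), B = 1L, r = rep(1L, nrow(s)))
  list(y = as.numeric(res$y), z = as.numeric(res$z))
}

#' Multi-head global attention
#'
#' Applies `n_heads` independent [global_attention_head()] layers and
#' concatenates their outputs in head order; with the default configuration
#' (`d_value = d_global / n_heads`) the result has dimension `d_global`.
#'
#' @param x Global state vector.
#' @param s `L x d_local` matrix of per-position states.
#' @param heads List of heads, each a list with `Wq`, `Wk`, `Wv`.
#' @return List with `y` (length `n_heads * d_value`) and `z` (matrix
#'   `n_heads x L`, one attention distribution per head).
#' @export
multi_head_global_attention <- function(x, s, heads) {
  outs <- lapply(heads, function(h) global_attention_head(x, s, h$Wq, h$Wk, h$Wv))
  list(y = unlist(lapply(outs, `[[`, "y"), use.names = FALSE),
       z = do.call(rbind, lapply(outs, `[[`, "z")))
}
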