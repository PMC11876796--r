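## Standard post-norm transformer encoder layer applied independently to each
## series along its time axis (no cross-node mixing; the graph attention
## stage handles that).  Rows of H are ordered (sample, node, time) with time
## fastest, so each series occupies `block` contiguous rows.

## Output projections start small (near-identity block): residual+norm then
## dominates at init, so input structure (values, position encodings)
## survives into downstream attention scores instead of being scrambled by
## random projections.
transformer_init <- function(d, ff_mult = 2) {
  tf <- list(wq = lin_init(d, d), wk = lin_init(d, d), wv = lin_init(d, d),
             wo = lin_init(d, d, scale = 0.02), ln1 = ln_init(d), ln2 = ln_init(d),
             ffn = mlp2_init(d, ff_mult * d, d))
  tf$ffn$l2$W <- tf$ffn$l2$W * 0.1
  tf
}

transformer_fwd <- function(H, p, block, nh, causal = FALSE) {
  R <- nrow(H); d <- ncol(H)
  dh <- d %/% nh
  cmask <- if (causal) outer(seq_len(block), seq_len(block), "<") * -1e30 else NULL
  n_blocks <- R %/% block
  Q <- linear_fwd(H, p$wq)$out
  K <- linear_fwd(H, p$wk)$out
  V <- linear_fwd(H, p$wv)$out
  ctx <- matrix(0, R, d)
  Pcache <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * block + 1):(b * block)
    Pb <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) / sqrt(dh)
      if (causal) S <- S + cmask
      P <- softmax_rows(S)
      ctx[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      Pb[[h]] <- P
    }
    Pcache[[b]] <- Pb
  }
  O <- linear_fwd(ctx, p$wo)
  u1 <- layernorm_fwd(H + O$out, p$ln1)
  f <- mlp2_fwd(u1$out, p$ffn)
  u2 <- layernorm_fwd(u1$out + f$out, p$ln2)
  list(out = u2$out,
       cache = list(H = H, Q = Q, K = K, V = V, ctx = ctx, P = Pcache,
                    u1 = u1, f = f, u2 = u2, block = block, nh = nh))
}

transformer_bwd <- function(p, cache, gout) {
  d <- ncol(gout); nh <- cache$nh; dh <- d %/% nh
  block <- cache$block
  n_blocks <- nrow(gout) %/% block
  b2 <- layernorm_bwd(p$ln2, cache$u2$cache, gout)
  gf <- mlp2_bwd(p$ffn, cache$f$cache, b2$gin)
  gu1 <- b2$gin + gf$gin
  b1 <- layernorm_bwd(p$ln1, cache$u1$cache, gu1)
  gH <- b1$gin
  go <- linear_bwd(p$wo, list(X = cache$ctx), b1$gin)
  gctx <- go$gin
  gQ <- matrix(0, nrow(gout), d); gK <- gQ; gV <- gQ
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * block + 1):(b * block)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- cache$P[[b]][[h]]
      gc_b <- gctx[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      gP <- tcrossprod(gc_b, Vb)
      gV[rows, cols] <- crossprod(P, gc_b)
      gS <- P * (gP - rowSums(gP * P))
      gS <- gS / sqrt(dh)
      gQ[rows, cols] <- gS %*% cache$K[rows, cols, drop = FALSE]
      gK[rows, cols] <- crossprod(gS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  bq <- linear_bwd(p$wq, list(X = cache$H), gQ)
  bk <- linear_bwd(p$wk, list(X = cache$H), gK)
  bv <- linear_bwd(p$wv, list(X = cache$H), gV)
  gH <- gH + bq$gin + bk$gin + bv$gin
  list(gin = gH,
       grads = list(wq = bq$grads, wk = bk$grads, wv = bv$grads, wo = go$grads,
                    ln1 = b1$grads, ln2 = b2$grads, ffn = gf$grads))
}
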