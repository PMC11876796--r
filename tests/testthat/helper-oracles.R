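# Independent brute-force reference implementations.  These enumerate every
# (query, key) pair with plain loops and never touch the package's fused
# kernels, so agreement is evidence of correctness rather than tautology.

st <- asNamespace("stcausal")

# Attention weights per query over the graph-restricted context.
oracle_alpha <- function(H, A, Wq, Wk, n_heads) {
  N <- dim(H)[1]; TT <- dim(H)[2]; d <- dim(H)[3]
  dh <- d %/% n_heads
  out <- list()
  for (i in seq_len(N)) for (t in seq_len(TT)) {
    nbr <- which(A[i, ] != 0)
    keys <- expand.grid(j = nbr, tp = seq_len(TT))
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      s <- apply(keys, 1, function(k) {
        q <- as.vector(Wq %*% H[i, t, ])[cols]
        kk <- as.vector(Wk %*% H[k[1], k[2], ])[cols]
        sum(q * kk) / sqrt(dh)
      })
      a <- exp(s - max(s)); a <- a / sum(a)
      for (r in seq_len(nrow(keys)))
        out[[length(out) + 1]] <- data.frame(
          query_node = i, query_t = t, key_node = keys$j[r], key_t = keys$tp[r],
          head = h, alpha = a[r])
    }
  }
  do.call(rbind, out)
}

# Full gated attention output for one query cell, given per-pair beta values
# supplied as a function beta_fn(i, t, j, tp).
oracle_sca_cell <- function(H, A, params, i, t, n_heads, beta_fn) {
  N <- dim(H)[1]; TT <- dim(H)[2]; d <- dim(H)[3]
  dh <- d %/% n_heads
  nbr <- which(A[i, ] != 0)
  out <- numeric(d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    s <- c(); v <- list(); b <- c()
    for (j in nbr) for (tp in seq_len(TT)) {
      q <- as.vector(params$Wq %*% H[i, t, ])[cols]
      kk <- as.vector(params$Wk %*% H[j, tp, ])[cols]
      s <- c(s, sum(q * kk) / sqrt(dh))
      v[[length(v) + 1]] <- message_value(H[i, t, ], H[j, tp, ], params$msg)[cols]
      b <- c(b, beta_fn(i, t, j, tp))
    }
    a <- exp(s - max(s)); a <- a / sum(a)
    Z <- sum(b * a)
    acc <- numeric(dh)
    for (r in seq_along(a)) acc <- acc + b[r] * a[r] * v[[r]]
    out[cols] <- acc / max(Z, 1e-8)
  }
  out
}

# Gate probability for a pair, by the direct formula.
oracle_rho <- function(h_q, h_k, params) {
  pre <- sum(params$wc1 * (params$Wqc %*% h_q)) +
    sum(params$wc2 * (params$Wkc %*% h_k)) + (params$bc %||% 0)
  1 / (1 + exp(-pre))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Prompt-decoder prediction for a single embedding row, by enumeration.
oracle_pbd_row <- function(h, dec, n_heads) {
  d <- length(h); dh <- d %/% n_heads
  NP <- nrow(dec$prompts)
  q <- as.vector(dec$wq$W %*% h) + dec$wq$b
  ctx <- numeric(d)
  for (hh in seq_len(n_heads)) {
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    s <- numeric(NP)
    for (n in seq_len(NP)) {
      kn <- as.vector(dec$wk$W %*% dec$prompts[n, ]) + dec$wk$b
      s[n] <- sum(q[cols] * kn[cols]) / sqrt(dh)
    }
    a <- exp(s - max(s)); a <- a / sum(a)
    for (n in seq_len(NP)) {
      vn <- as.vector(dec$wv$W %*% dec$prompts[n, ]) + dec$wv$b
      ctx[cols] <- ctx[cols] + a[n] * vn[cols]
    }
  }
  u <- as.vector(dec$proj$W %*% ctx) + dec$proj$b
  mu <- mean(u); vv <- mean((u - mu)^2)
  xhat <- (u - mu) / sqrt(vv + 1e-5)
  u2 <- xhat * dec$ln$gamma + dec$ln$beta
  sum(dec$head$W * u2) + dec$head$b
}

# Max-pool a per-pair gate table (from encode()'s gate_states) into the
# node-level causal matrix, by four nested loops.
oracle_causal_matrix <- function(gate_df, N, TT) {
  W <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    sub <- gate_df[gate_df$query_node == i & gate_df$key_node == j, ]
    if (nrow(sub) > 0) W[i, j] <- max(sub$beta) / TT^2
  }
  W
}

rand_sca_instance <- function(N = 3, TT = 4, d = 4, n_heads = 1, p_edge = 0.7) {
  A <- matrix(rbinom(N * N, 1, p_edge), N)
  diag(A) <- 1
  H <- array(rnorm(N * TT * d), c(N, TT, d))
  params <- st$sca_params(d)
  list(A = A, H = H, params = params)
}
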