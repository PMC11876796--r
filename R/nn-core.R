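## Minimal dense-layer toolkit with hand-written backpropagation.
## Parameters live in nested named lists with numeric matrices/vectors at the
## leaves; gradients mirror the same structure.  All "row" matrices are
## (cells x d): one row per (sample, node, time) cell.

lin_init <- function(n_out, n_in, scale = NULL) {
  s <- scale %||% sqrt(2 / (n_in + n_out))
  list(W = matrix(rnorm(n_out * n_in, sd = s), n_out, n_in), b = numeric(n_out))
}

addrow <- function(M, v) M + rep(v, rep.int(nrow(M), length(v)))

linear_fwd <- function(X, p) {
  list(out = addrow(X %*% t(p$W), p$b), cache = list(X = X))
}

linear_bwd <- function(p, cache, gout) {
  list(gin = gout %*% p$W,
       grads = list(W = crossprod(gout, cache$X), b = colSums(gout)))
}

mlp2_init <- function(n_in, n_hidden, n_out, scale1 = NULL) {
  list(l1 = lin_init(n_hidden, n_in, scale = scale1), l2 = lin_init(n_out, n_hidden))
}

mlp2_fwd <- function(X, p) {
  f1 <- linear_fwd(X, p$l1)
  h <- f1$out * (f1$out > 0)
  f2 <- linear_fwd(h, p$l2)
  list(out = f2$out, cache = list(X = X, pre1 = f1$out, h = h))
}

mlp2_bwd <- function(p, cache, gout) {
  b2 <- linear_bwd(p$l2, list(X = cache$h), gout)
  gh <- b2$gin * (cache$pre1 > 0)
  b1 <- linear_bwd(p$l1, list(X = cache$X), gh)
  list(gin = b1$gin, grads = list(l1 = b1$grads, l2 = b2$grads))
}

ln_init <- function(d) list(gamma = rep(1, d), beta = rep(0, d))

## Layer norm over the d embedding channels of each row.
layernorm_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- addrow(xhat * rep(p$gamma, rep.int(nrow(X), length(p$gamma))), p$beta)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(p, cache, gout) {
  d <- ncol(gout)
  gxhat <- gout * rep(p$gamma, rep.int(nrow(gout), d))
  xhat <- cache$xhat
  gx <- (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat)) * cache$inv
  list(gin = gx,
       grads = list(gamma = colSums(gout * xhat), beta = colSums(gout)))
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

## Grouped softmax over a flat score vector with integer group ids (queries).
## Groups need not be contiguous.  Returns probabilities aligned with s.
grouped_softmax <- function(s, group, n_groups) {
  mx <- grouped_max(s, group, n_groups)
  e <- exp(s - mx[group])
  tot <- rowsum_vec(e, group, n_groups)
  e / tot[group]
}

grouped_max <- function(s, group, n_groups) {
  dt <- data.table::data.table(g = group, s = s)
  mx <- dt[, max(s), keyby = "g"]
  out <- rep(-Inf, n_groups)
  out[mx$g] <- mx$V1
  out
}

rowsum_vec <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

## Accumulate rows of G (m x d) into an (n x d) matrix by index (length m).
index_rowsum <- function(G, index, n) {
  rs <- rowsum(G, index)
  out <- matrix(0, n, ncol(G))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

head_mask <- function(d, nh) {
  dh <- d %/% nh
  Hm <- matrix(0, d, nh)
  for (h in seq_len(nh)) Hm[((h - 1) * dh + 1):(h * dh), h] <- 1
  Hm
}

## ---- parameter-tree utilities ------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) return(lapply(x, function(e) tree_map(f, e)))
  f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (k in seq_along(x)) out[[k]] <- tree_map2(f, x[[k]], y[[k]])
    return(out)
  }
  f(x, y)
}

tree_zero <- function(x) tree_map(function(v) v * 0, x)

tree_add <- function(x, y) {
  if (is.null(y)) return(x)
  tree_map2(`+`, x, y)
}

## ---- Adam with cosine learning-rate schedule ---------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

cosine_lr <- function(epoch, max_epochs, lr0, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(1, max_epochs - 1)))
}

## Sinusoidal position encodings, T x d.
positional_encoding <- function(TT, d) {
  pos <- matrix(seq_len(TT) - 1, TT, d %/% 2)
  i <- matrix(seq_len(d %/% 2) - 1, TT, d %/% 2, byrow = TRUE)
  ang <- pos / (10000^(2 * i / d))
  pe <- matrix(0, TT, d)
  pe[, seq(1, d, 2)] <- sin(ang)
  pe[, seq(2, d, 2)] <- cos(ang)
  pe
}
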