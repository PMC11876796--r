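## Spatiotemporal causal attention (SCA).
##
## For each query cell (i, t), the context is every time step of every graph
## neighbour of i (self-loops included).  Each (query, key) pair carries
##   alpha — a softmax correlation weight over the whole context, and
##   beta  — a Bernoulli causal gate with learned probability rho,
##            relaxed by binary Gumbel-Softmax during training and hard
##            thresholded at 0.5 during evaluation.
## The output is sum(beta * alpha * message) / Z with Z = sum(beta * alpha),
## floored at 1e-8; Z = 1 exactly when every gate is open.

Z_FLOOR <- 1e-8
RHO_EPS <- 1e-7

#' Initialise SCA parameters
#'
#' @param d Embedding width (divisible by `n_heads`).
#' @return Parameter list: query/key scorers `Wq`, `Wk`; gate scorers `Wqc`,
#'   `Wkc` with combining weights `wc1`, `wc2`; message MLP (two layers,
#'   2d -> d -> d, ReLU).
#' @export
sca_params <- function(d, gate_init = 0.9) {
  ## identity-scaled scorers: with sinusoidal position encodings in the
  ## embeddings, Q.K then peaks at time-aligned keys from the first step,
  ## giving the attention a same-time prior that training refines.  The
  ## message MLP starts near an identity on the key embedding (shifted ReLU
  ## operating in its linear region), so aggregation initially passes
  ## neighbour content through rather than random mixtures.
  list(Wq = diag(2, d) + matrix(rnorm(d * d, sd = 0.02), d),
       Wk = diag(2, d) + matrix(rnorm(d * d, sd = 0.02), d),
       Wqc = lin_init(d, d)$W, Wkc = lin_init(d, d)$W,
       wc1 = rnorm(d, sd = sqrt(1 / d)), wc2 = rnorm(d, sd = sqrt(1 / d)),
       bc = log(gate_init / (1 - gate_init)),
       msg = list(W1q = matrix(rnorm(d * d, sd = 0.02), d),
                  W1k = diag(1, d) + matrix(rnorm(d * d, sd = 0.02), d),
                  b1 = rep(2, d),
                  W2 = diag(1, d) + matrix(rnorm(d * d, sd = 0.02), d),
                  b2 = rep(-2, d)))
}

## Pair index structure for one sample: all (query cell, key cell) pairs
## allowed by the graph, sorted by query so that each query's context is a
## contiguous run.  Row index of cell (i, t) is (i-1)*T + t.  `q_ptr` /
## `k_ptr` are 0-based cumulative counts for segment reductions; `classes`
## groups queries with equal context size for the segment-max kernel;
## `perm_k` sorts pairs by key.
sca_pairs <- function(A, TT, constrained = FALSE) {
  N <- nrow(A)
  nbrs <- lapply(seq_len(N), function(i) which(A[i, ] != 0))
  deg <- lengths(nbrs)
  if (any(deg == 0))
    stopf("query node %d has an empty neighbourhood (no self-loop?)",
          which(deg == 0)[1])
  edge_tab <- cbind(query = rep(seq_len(N), deg), key = unlist(nbrs))
  qs <- ks <- es <- vector("list", N)
  e0 <- 0L
  for (i in seq_len(N)) {
    nb <- nbrs[[i]]; di <- length(nb)
    keys_i <- rep((nb - 1L) * TT, each = TT) + rep(seq_len(TT), di)
    eids_i <- rep(e0 + seq_len(di), each = TT)
    if (constrained) {
      tks <- rep(seq_len(TT), di)
      qs[[i]] <- unlist(lapply(seq_len(TT), function(t)
        rep.int((i - 1L) * TT + t, sum(tks <= t))))
      ks[[i]] <- unlist(lapply(seq_len(TT), function(t) keys_i[tks <= t]))
      es[[i]] <- unlist(lapply(seq_len(TT), function(t) eids_i[tks <= t]))
    } else {
      qs[[i]] <- rep((i - 1L) * TT + seq_len(TT), each = di * TT)
      ks[[i]] <- rep.int(keys_i, TT)
      es[[i]] <- rep.int(eids_i, TT)
    }
    e0 <- e0 + di
  }
  out <- list(qi = unlist(qs), ki = unlist(ks), edge = unlist(es),
              edge_tab = edge_tab, N = N, TT = TT, n_rows = N * TT,
              n_edges = e0, constrained = constrained)
  sca_aux(out)
}

## Derive the query-segment pointer from a query-sorted pair list.
sca_aux <- function(pairs) {
  ctx <- tabulate(pairs$qi, pairs$n_rows)
  pairs$q_ptr <- c(0, cumsum(ctx))
  pairs
}

## Offset a single-sample pair structure across a batch of B samples; all
## reduction structures replicate blockwise.
sca_pairs_batch <- function(pairs, B) {
  if (B == 1) return(pairs)
  P0 <- length(pairs$qi); R0 <- pairs$n_rows
  roff <- rep((seq_len(B) - 1L) * R0, each = P0)
  out <- list(qi = rep.int(pairs$qi, B) + roff,
              ki = rep.int(pairs$ki, B) + roff,
              edge = rep.int(pairs$edge, B),
              edge_tab = pairs$edge_tab, N = pairs$N, TT = pairs$TT,
              n_rows = R0 * B, n_edges = pairs$n_edges,
              constrained = pairs$constrained)
  ctx0 <- diff(pairs$q_ptr)
  out$q_ptr <- c(0, cumsum(rep.int(ctx0, B)))
  out
}

## Core forward on flat rows.  H: (R x d); pairs: (batched) pair structure.
## P-sized buffers are kept transposed (d x P) for the compiled kernels;
## dense projections stay in BLAS.
sca_fwd <- function(H, pairs, p, nh, tau, mode = "train", no_gate = FALSE) {
  R <- nrow(H); d <- ncol(H)
  qi <- pairs$qi; ki <- pairs$ki
  P <- length(qi)
  Hm <- head_mask(d, nh)
  QT <- tcrossprod(p$Wq, H)          # d x R
  KT <- tcrossprod(p$Wk, H)
  A1T <- tcrossprod(p$msg$W1q, H)
  B1T <- tcrossprod(p$msg$W1k, H)
  if (no_gate) {
    aq <- ak <- numeric(0)
  } else {
    aq <- as.vector(H %*% crossprod(p$Wqc, p$wc1))
    ak <- as.vector(H %*% crossprod(p$Wkc, p$wc2))
  }
  kr <- sca_pairs_fwd_cpp(QT, KT, A1T, B1T, p$msg$b1, aq, ak, qi, ki,
                          pairs$q_ptr, nh, !no_gate)
  if (no_gate) {
    rho <- NULL; beta <- rep(1, P); u <- NULL
  } else if (mode == "train") {
    u <- matrix(runif(2 * P), P, 2)
    gf <- gate_fwd_cpp(kr$pre + p$bc, tau, u[, 1], u[, 2], TRUE, RHO_EPS)
    rho <- gf$rho; beta <- gf$beta
  } else {
    u <- NULL
    gf <- gate_fwd_cpp(kr$pre + p$bc, tau, numeric(0), numeric(0), FALSE, RHO_EPS)
    rho <- gf$rho; beta <- gf$beta
  }
  ag <- sca_agg_cpp(kr$h1T, kr$alphaT, beta, pairs$q_ptr, R, nh)
  Z <- t(ag$ZT)                           # R x nh
  Zf <- pmax(Z, Z_FLOOR)
  dh <- d %/% nh
  num <- matrix(0, R, d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows_h <- ((h - 1) * d + 1):(h * d)
    num[, cols] <- t(p$msg$W2[cols, , drop = FALSE] %*% ag$AggT[rows_h, , drop = FALSE]) +
      outer(Z[, h], p$msg$b2[cols])
  }
  out <- num / (Zf %*% t(Hm))
  flagged <- which(apply(Z < Z_FLOOR, 1, all))
  list(out = out,
       cache = list(H = H, QT = QT, KT = KT, alphaT = kr$alphaT, rho = rho,
                    beta = beta, u = u, h1T = kr$h1T, AggT = ag$AggT, Z = Z,
                    num = num, pairs = pairs, nh = nh, tau = tau,
                    mode = mode, no_gate = no_gate),
       rho = rho, beta = beta, flagged = flagged)
}

## Backward.  g_rho_extra is the per-rho gradient of the l1 penalty (a
## scalar, added to every rho's gradient).
sca_bwd <- function(p, cache, gout, g_rho_extra = 0) {
  pairs <- cache$pairs
  qi <- pairs$qi; ki <- pairs$ki
  H <- cache$H
  R <- nrow(H); d <- ncol(H); nh <- cache$nh
  dh <- d %/% nh
  P <- length(qi)
  Hm <- head_mask(d, nh)
  Zf <- pmax(cache$Z, Z_FLOOR)
  Zexp <- Zf %*% t(Hm)
  gnum <- gout / Zexp
  gZ <- -((gout * cache$num / Zexp^2) %*% Hm)
  gZ[cache$Z < Z_FLOOR] <- 0
  ## per-head backprojected gradients and the b2 contribution to gw
  Gstack <- matrix(0, d * nh, R)
  gZb <- t(gZ)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows_h <- ((h - 1) * d + 1):(h * d)
    Gstack[rows_h, ] <- crossprod(p$msg$W2[cols, , drop = FALSE],
                                  t(gnum[, cols, drop = FALSE]))
    gZb[h, ] <- gZb[h, ] + as.vector(gnum[, cols, drop = FALSE] %*%
                                       p$msg$b2[cols])
  }
  kb <- sca_agg_bwd_cpp(cache$h1T, cache$alphaT, cache$beta, Gstack, gZb,
                        cache$QT, cache$KT, qi, ki, pairs$q_ptr, nh)
  grads <- list(Wq = kb$gQT %*% H, Wk = kb$gKT %*% H,
                Wqc = matrix(0, d, d), Wkc = matrix(0, d, d),
                wc1 = numeric(d), wc2 = numeric(d), bc = 0,
                msg = list(W1q = NULL, W1k = NULL, b1 = NULL, W2 = NULL, b2 = NULL))
  gH <- crossprod(kb$gQT, p$Wq) + crossprod(kb$gKT, p$Wk)
  ## gate branch
  if (!cache$no_gate) {
    rho <- cache$rho
    gpre <- if (cache$mode == "train")
      gate_bwd_cpp(kb$gbeta, rho, cache$beta, cache$tau, g_rho_extra)
    else g_rho_extra * rho * (1 - rho)
    grads$bc <- sum(gpre)
    gaq <- accum_vec_cpp(gpre, qi, R)
    gak <- accum_vec_cpp(gpre, ki, R)
    u1v <- as.vector(crossprod(p$Wqc, p$wc1))
    u2v <- as.vector(crossprod(p$Wkc, p$wc2))
    gu1 <- as.vector(crossprod(H, gaq))   # d-vector
    gu2 <- as.vector(crossprod(H, gak))
    grads$Wqc <- outer(p$wc1, gu1)
    grads$Wkc <- outer(p$wc2, gu2)
    grads$wc1 <- as.vector(p$Wqc %*% gu1)
    grads$wc2 <- as.vector(p$Wkc %*% gu2)
    gH <- gH + gaq %*% t(u1v) + gak %*% t(u2v)
  }
  ## message MLP: W2/b2 grads via the aggregates, then the hidden layer
  gW2 <- matrix(0, d, d)
  gb2 <- numeric(d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows_h <- ((h - 1) * d + 1):(h * d)
    gW2[cols, ] <- tcrossprod(t(gnum[, cols, drop = FALSE]),
                              cache$AggT[rows_h, , drop = FALSE])
    gb2[cols] <- as.vector(crossprod(gnum[, cols, drop = FALSE], cache$Z[, h]))
  }
  grads$msg$W2 <- gW2
  grads$msg$b2 <- gb2
  gh1T <- kb$gh1T * (cache$h1T > 0)
  grads$msg$b1 <- rowSums(gh1T)
  gA1T <- accum_cols_cpp(gh1T, qi, R)
  gB1T <- accum_cols_cpp(gh1T, ki, R)
  grads$msg$W1q <- gA1T %*% H
  grads$msg$W1k <- gB1T %*% H
  gH <- gH + crossprod(gA1T, p$msg$W1q) + crossprod(gB1T, p$msg$W1k)
  list(gin = gH, grads = grads)
}

#' Binary Gumbel-Softmax gate
#'
#' Differentiable relaxation of `beta ~ Bernoulli(rho)`:
#' `beta = exp((log rho + g1)/tau) / (exp((log rho + g1)/tau) +
#' exp((log(1-rho) + g2)/tau))` with `g = -log(-log(u))`, `u ~ Uniform(0,1)`.
#' As `tau -> 0` the gate hardens to the Gumbel-max Bernoulli sample.
#'
#' @param rho Gate probabilities in (0, 1).
#' @param tau Positive temperature.
#' @param u1,u2 Uniform draws in (0, 1) (clamped away from the endpoints).
#' @return Soft gates in (0, 1), same length as `rho`.
#' @export
gumbel_gate <- function(rho, tau, u1, u2) {
  if (tau <= 0) stopf("tau must be positive")
  u1 <- pmin(pmax(u1, 1e-6), 1 - 1e-6)
  u2 <- pmin(pmax(u2, 1e-6), 1 - 1e-6)
  g1 <- -log(-log(u1)); g2 <- -log(-log(u2))
  z <- (log(rho) + g1 - log1p(-rho) - g2) / tau
  sigmoid(z)
}

#' Message function: MLP on the concatenated query and key embeddings
#'
#' @param h_q,h_k Embedding vectors of length d (or matrices with d columns).
#' @param msg Message-MLP parameters (from [sca_params()]`$msg`).
#' @return Message vector(s) of length d.
#' @export
message_value <- function(h_q, h_k, msg) {
  h_q <- rbind(h_q); h_k <- rbind(h_k)
  pre1 <- h_q %*% t(msg$W1q) + h_k %*% t(msg$W1k)
  pre1 <- sweep(pre1, 2, msg$b1, "+")
  h1 <- pre1 * (pre1 > 0)
  out <- sweep(h1 %*% t(msg$W2), 2, msg$b2, "+")
  if (nrow(out) == 1) as.vector(out) else out
}

## Shape an (N, T, d) array into flat rows (time fastest) and back.
flatten_ntd <- function(Harr) {
  N <- dim(Harr)[1]; TT <- dim(Harr)[2]; d <- dim(Harr)[3]
  H <- matrix(0, N * TT, d)
  for (i in seq_len(N)) H[((i - 1) * TT + 1):(i * TT), ] <- Harr[i, , ]
  H
}

unflatten_ntd <- function(H, N, TT) {
  d <- ncol(H)
  arr <- array(0, c(N, TT, d))
  for (i in seq_len(N)) arr[i, , ] <- H[((i - 1) * TT + 1):(i * TT), ]
  arr
}

#' Correlation (attention) weights over graph-restricted contexts
#'
#' Scaled dot-product scores `s = (Wq h_q)' (Wk h_k) / sqrt(d_head)`,
#' softmax-normalised over each query's full context (all time steps of all
#' graph neighbours), per head.
#'
#' @param H N x T x d embedding array.
#' @param A Adjacency matrix.
#' @param params [sca_params()].
#' @param n_heads Number of attention heads.
#' @param constrained Restrict keys to `t' <= t`.
#' @return Data frame with query/key node and time indices and one alpha
#'   column per head; alphas sum to 1 per query within each head.
#' @export
correlation_weights <- function(H, A, params, n_heads = 1, constrained = FALSE) {
  N <- dim(H)[1]; TT <- dim(H)[2]; d <- dim(H)[3]
  Hm <- flatten_ntd(H)
  pairs <- sca_pairs(A, TT, constrained)
  dh <- d %/% n_heads
  Q <- Hm %*% t(params$Wq); K <- Hm %*% t(params$Wk)
  out <- pair_frame(pairs)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    s <- rowSums(Q[pairs$qi, cols, drop = FALSE] *
                   K[pairs$ki, cols, drop = FALSE]) / sqrt(dh)
    out[[paste0("alpha", h)]] <- grouped_softmax(s, pairs$qi, N * TT)
  }
  out
}

#' Causal gate probabilities for every graph-restricted pair
#'
#' `rho = sigmoid(wc' [Wqc h_q ; Wkc h_k])`, one probability per
#' (query cell, key cell) pair with the key's node adjacent to the query's.
#'
#' @inheritParams correlation_weights
#' @return Data frame of pairs with a `rho` column, strictly inside (0, 1).
#' @export
causal_probability <- function(H, A, params, constrained = FALSE) {
  TT <- dim(H)[2]
  Hm <- flatten_ntd(H)
  pairs <- sca_pairs(A, TT, constrained)
  aq <- as.vector(Hm %*% crossprod(params$Wqc, params$wc1))
  ak <- as.vector(Hm %*% crossprod(params$Wkc, params$wc2))
  bc <- params$bc %||% 0
  out <- pair_frame(pairs)
  out$rho <- pmin(pmax(sigmoid(aq[pairs$qi] + ak[pairs$ki] + bc), RHO_EPS), 1 - RHO_EPS)
  out
}

pair_frame <- function(pairs) {
  TT <- pairs$TT
  data.frame(query_node = (pairs$qi - 1L) %/% TT + 1L,
             query_t = (pairs$qi - 1L) %% TT + 1L,
             key_node = (pairs$ki - 1L) %/% TT + 1L,
             key_t = (pairs$ki - 1L) %% TT + 1L)
}

#' Spatiotemporal causal attention forward pass
#'
#' @param H N x T x d embedding array.
#' @param A Adjacency matrix (nonzero entries define neighbourhoods;
#'   self-loops recommended).
#' @param params [sca_params()].
#' @param mode `"train"` (soft Gumbel-sampled gates) or `"eval"`
#'   (deterministic hard gates `beta = 1[rho >= 0.5]`).
#' @param n_heads,tau Head count and Gumbel temperature.
#' @param no_gate Force every gate open (`beta = 1`): plain neighbour
#'   attention, in which case the normaliser Z is exactly 1.
#' @param constrained Restrict keys to `t' <= t`.
#' @return List: `H_out` (N x T x d), and `gate_state` — a data frame of all
#'   pairs with `rho`, `beta` and head-averaged `alpha`, plus attribute
#'   `"flagged"` marking queries whose gates were all closed (output zeroed).
#' @export
sca_forward <- function(H, A, params, mode = c("eval", "train"), n_heads = 1,
                        tau = 0.5, no_gate = FALSE, constrained = FALSE) {
  mode <- match.arg(mode)
  N <- dim(H)[1]; TT <- dim(H)[2]
  Hm <- flatten_ntd(H)
  pairs <- sca_pairs(A, TT, constrained)
  f <- sca_fwd(Hm, pairs, params, nh = n_heads, tau = tau, mode = mode,
               no_gate = no_gate)
  gs <- pair_frame(pairs)
  gs$rho <- if (is.null(f$rho)) rep(NA_real_, length(pairs$qi)) else f$rho
  gs$beta <- f$beta
  gs$alpha <- colMeans(f$cache$alphaT)
  attr(gs, "flagged") <- f$flagged
  list(H_out = unflatten_ntd(f$out, N, TT), gate_state = gs, Z = f$cache$Z)
}

#' Export a gate state table to TSV
#'
#' @param gate_state Gate-state data frame from [sca_forward()] (optionally
#'   with a `layer` column added by [encode()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gate_state <- function(gate_state, path) {
  utils::write.table(gate_state, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
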