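## Prompt Based Decoder: each cell embedding queries a bank of learnable
## prompt vectors with multi-head scaled dot-product attention; keys and
## values are projected prompts.  The attended context passes through a
## linear projection + layer norm and a final linear head to one scalar per
## cell.  The bank realises the frontdoor adjustment's marginal over inputs:
## the prompts learn the dataset's global context, so the prediction for a
## cell is conditioned through the embedding and marginalised over contexts
## rather than free to exploit confounder shortcuts.

## Head-blocked prompt attention: keys/values of all heads are packed into
## block-diagonal matrices so scores and contexts come from two large GEMMs
## instead of many thin per-head products.
pbd_block_kv <- function(M, nh) {
  d <- ncol(M); dh <- d %/% nh; NP <- nrow(M)
  B <- matrix(0, d, nh * NP)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    B[cols, ((h - 1) * NP + 1):(h * NP)] <- t(M[, cols, drop = FALSE])
  }
  B
}

pbd_fwd <- function(H, dec, nh) {
  R <- nrow(H); d <- ncol(H); dh <- d %/% nh
  NP <- nrow(dec$prompts)
  Q <- linear_fwd(H, dec$wq)$out
  K <- linear_fwd(dec$prompts, dec$wk)$out
  V <- linear_fwd(dec$prompts, dec$wv)$out
  Kb <- pbd_block_kv(K, nh)
  Vb <- pbd_block_kv(V, nh)
  S <- Q %*% Kb / sqrt(dh)                     # R x (nh*NP)
  row_softmax_blocked_cpp(S, NP)               # in place, per head block
  ctx <- Q + S %*% t(Vb)                       # residual query + attended bank
  pr <- linear_fwd(ctx, dec$proj)
  ln <- layernorm_fwd(pr$out, dec$ln)
  hd <- linear_fwd(ln$out, dec$head)
  list(out = as.vector(hd$out),
       cache = list(H = H, Q = Q, Kb = Kb, Vb = Vb, ctx = ctx, attn = S,
                    pr = pr, ln = ln, nh = nh, NP = NP))
}

pbd_bwd <- function(dec, cache, gy, freeze_bank = FALSE) {
  d <- ncol(cache$H); nh <- cache$nh; dh <- d %/% nh
  NP <- cache$NP
  ghead <- linear_bwd(dec$head, list(X = cache$ln$out), matrix(gy, ncol = 1))
  gln <- layernorm_bwd(dec$ln, cache$ln$cache, ghead$gin)
  gproj <- linear_bwd(dec$proj, list(X = cache$ctx), gln$gin)
  gctx <- gproj$gin
  gVb <- crossprod(cache$attn, gctx)           # (nh*NP) x d
  gS <- gctx %*% cache$Vb                      # R x (nh*NP)
  row_softmax_bwd_blocked_cpp(gS, cache$attn, NP, 1 / sqrt(dh))
  gQ <- gctx + gS %*% t(cache$Kb)              # residual + attention paths
  gKb <- crossprod(gS, cache$Q)                # (nh*NP) x d
  gV <- matrix(0, NP, d)
  gK <- matrix(0, NP, d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    rows <- ((h - 1) * NP + 1):(h * NP)
    gV[, cols] <- gVb[rows, cols, drop = FALSE]
    gK[, cols] <- gKb[rows, cols, drop = FALSE]
  }
  bq <- linear_bwd(dec$wq, list(X = cache$H), gQ)
  bk <- linear_bwd(dec$wk, list(X = dec$prompts), gK)
  bv <- linear_bwd(dec$wv, list(X = dec$prompts), gV)
  gprompts <- if (freeze_bank) matrix(0, NP, d) else bk$gin + bv$gin
  list(gin = bq$gin,
       grads = list(prompts = gprompts, wq = bq$grads, wk = bk$grads,
                    wv = bv$grads, proj = gproj$grads, ln = gln$grads,
                    head = ghead$grads))
}

#' Prompt-based decoder forward pass
#'
#' Scaled dot-product attention from each cell embedding over the prompt
#' bank (projected keys/values), a linear projection with layer norm, and a
#' linear scalar head.
#'
#' @param H N x T x d embedding array (or an (cells x d) matrix).
#' @param dec Decoder parameters (`$decoder` of [init_model_params()] with
#'   `decoder = "pbd"`).
#' @param n_heads Attention heads.
#' @return N x T matrix of predictions (or a vector for matrix input).
#' @export
pbd_forward <- function(H, dec, n_heads = 4) {
  if (is.matrix(H)) return(pbd_fwd(H, dec, n_heads)$out)
  N <- dim(H)[1]; TT <- dim(H)[2]
  y <- pbd_fwd(flatten_ntd(H), dec, n_heads)$out
  matrix(y, N, TT, byrow = TRUE)
}

#' Decoder variants for ablation studies
#'
#' `"pbd"` uses the learnable prompt bank; `"mlp"` replaces the decoder with
#' a per-cell perceptron (no global context); `"kmeans"` and `"sample"` run
#' the prompt decoder over a frozen externally supplied bank (e.g. K-means
#' centres of pre-trained embeddings, or sampled embeddings).
#'
#' @param H N x T x d embedding array.
#' @param mode One of `"pbd"`, `"mlp"`, `"kmeans"`, `"sample"`.
#' @param dec Decoder parameters.
#' @param n_heads Attention heads.
#' @param bank Frozen bank matrix (rows x d) for `"kmeans"`/`"sample"`; may
#'   also be a path to a TSV with one prompt per row.
#' @return N x T matrix of predictions.
#' @export
decoder_variant <- function(H, mode = c("pbd", "mlp", "kmeans", "sample"),
                            dec, n_heads = 4, bank = NULL) {
  mode <- match.arg(mode)
  if (mode == "pbd") return(pbd_forward(H, dec, n_heads))
  if (mode == "mlp") {
    Hm <- flatten_ntd(H)
    y <- mlp2_fwd(Hm, dec$mlp)$out
    return(matrix(as.vector(y), dim(H)[1], dim(H)[2], byrow = TRUE))
  }
  if (is.null(bank)) stopf("%s decoder mode requires an external bank", mode)
  if (is.character(bank)) {
    bank <- as.matrix(utils::read.table(bank, sep = "\t", header = FALSE))
    storage.mode(bank) <- "double"
  }
  if (ncol(bank) != dim(H)[3])
    stopf("bank has %d columns, embeddings have width %d", ncol(bank), dim(H)[3])
  dec$prompts <- unname(bank)
  pbd_forward(H, dec, n_heads)
}
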