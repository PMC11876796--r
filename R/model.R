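## Full network forward/backward on flat rows.  A batch of B windows of an
## N-series, T-step graph is laid out as R = B*N*T rows ordered (sample,
## node, time) with time fastest; xv/mv are the flattened values and mask.

model_fwd <- function(params, config, xv, mv, pairs, B, N, TT,
                      mode = "train") {
  d <- config$d
  L <- length(params$layers)
  nh <- config$n_heads
  in_mlp <- mlp2_fwd(matrix(xv, ncol = 1), params$input_mlp)
  H <- in_mlp$out * mv + outer(1 - mv, params$m)
  pe <- positional_encoding(TT, d)
  pe_rows <- pe[rep(seq_len(TT), B * N), , drop = FALSE]
  layer_caches <- vector("list", L)
  rho_list <- vector("list", L)
  for (l in seq_len(L)) {
    lp <- params$layers[[l]]
    if (config$no_skip) {
      Hskip <- H
      skip_mlp_cache <- NULL
    } else {
      sk <- mlp2_fwd(matrix(xv, ncol = 1), lp$skip_mlp)
      Hskip <- H + sk$out * mv + outer(1 - mv, params$m)
      skip_mlp_cache <- sk$cache
    }
    tf <- transformer_fwd(Hskip + pe_rows, lp$transformer, block = TT, nh = nh,
                          causal = config$constrained)
    Hin <- tf$out
    sca <- sca_fwd(Hin, pairs, lp$sca, nh = nh, tau = config$tau, mode = mode,
                   no_gate = config$no_gate)
    ln <- layernorm_fwd(Hin + sca$out, lp$ln_out)
    layer_caches[[l]] <- list(skip_mlp = skip_mlp_cache, tf = tf$cache,
                              sca = sca, ln = ln)
    rho_list[[l]] <- sca$rho
    H <- ln$out
  }
  if (config$decoder == "pbd") {
    dec <- pbd_fwd(H, params$decoder, nh)
    yhat <- dec$out
    dec_cache <- dec$cache
  } else {
    dec <- mlp2_fwd(H, params$decoder$mlp)
    yhat <- as.vector(dec$out)
    dec_cache <- dec$cache
  }
  list(yhat = yhat, H = H,
       in_mlp_cache = in_mlp$cache, layer_caches = layer_caches,
       dec_cache = dec_cache, rho_list = rho_list,
       xv = xv, mv = mv, pairs = pairs, B = B, N = N, TT = TT)
}

model_bwd <- function(params, config, fwd, gy, lambda_l1 = 0) {
  L <- length(params$layers)
  n_rho <- sum(vapply(fwd$rho_list, function(r) length(r %||% numeric(0)), 0))
  g_rho_extra <- if (n_rho > 0 && lambda_l1 > 0) lambda_l1 / n_rho else 0
  grads <- tree_zero(params)
  if (config$decoder == "pbd") {
    db <- pbd_bwd(params$decoder, fwd$dec_cache, gy)
    grads$decoder <- db$grads
    gH <- db$gin
  } else {
    db <- mlp2_bwd(params$decoder$mlp, fwd$dec_cache, matrix(gy, ncol = 1))
    grads$decoder$mlp <- db$grads
    gH <- db$gin
  }
  mv <- fwd$mv
  g_m <- numeric(config$d)
  for (l in rev(seq_len(L))) {
    lp <- params$layers[[l]]
    lc <- fwd$layer_caches[[l]]
    bl <- layernorm_bwd(lp$ln_out, lc$ln$cache, gH)
    grads$layers[[l]]$ln_out <- bl$grads
    bs <- sca_bwd(lp$sca, lc$sca$cache, bl$gin, g_rho_extra = g_rho_extra)
    grads$layers[[l]]$sca <- bs$grads
    gHin <- bl$gin + bs$gin
    bt <- transformer_bwd(lp$transformer, lc$tf, gHin)
    grads$layers[[l]]$transformer <- bt$grads
    gHskip <- bt$gin
    if (config$no_skip) {
      gH <- gHskip
    } else {
      gmlp_out <- gHskip * mv
      bm <- mlp2_bwd(lp$skip_mlp, lc$skip_mlp, gmlp_out)
      grads$layers[[l]]$skip_mlp <- bm$grads
      g_m <- g_m + colSums(gHskip * (1 - mv))
      gH <- gHskip
    }
  }
  bi <- mlp2_bwd(params$input_mlp, fwd$in_mlp_cache, gH * mv)
  grads$input_mlp <- bi$grads
  g_m <- g_m + colSums(gH * (1 - mv))
  grads$m <- g_m
  grads
}

## Flatten B windows (list of N x T matrices) into row vectors.
stack_windows <- function(Xw, Mw) {
  xv <- unlist(lapply(Xw, function(X) as.vector(t(X))))
  mv <- unlist(lapply(Mw, function(M) as.vector(t(M))))
  list(xv = xv, mv = mv)
}
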