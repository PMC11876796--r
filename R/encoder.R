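#' Model configuration
#'
#' Architectural hyperparameters for the imputation network.  Defaults follow
#' the reference configuration: embedding width 32, 2 encoder layers for
#' graphs up to 36 nodes (4 for larger), 4 attention heads, 1000 prompts,
#' Gumbel temperature 0.5 (fixed, no annealing).
#'
#' @param d Embedding width (divisible by `n_heads`).
#' @param L Number of encoder layers; if `NULL`, chosen from the node count
#'   at training time (2 when N <= 36, else 4).
#' @param n_heads Attention heads (correlation weights are per-head; the
#'   causal gate is shared across heads — one Granger verdict per pair).
#' @param n_prompts Prompt-bank size for the decoder.
#' @param tau Gumbel-Softmax temperature.
#' @param window_T Length of training windows.
#' @param ff_mult Transformer feedforward width multiplier.
#' @param decoder `"pbd"` (prompt decoder) or `"mlp"` (per-cell MLP head).
#' @param no_gate Ablation: force all causal gates open (plain attention).
#' @param no_graph Ablation: replace A with the identity (no cross-series
#'   attention).
#' @param constrained Ablation: restrict attention keys to `t' <= t`.
#' @param no_skip Ablation: disable the skip projection (layers reuse the
#'   previous layer's embeddings unchanged).
#' @return A list of class `model_config`.
#' @export
model_config <- function(d = 32, L = NULL, n_heads = 4, n_prompts = 1000,
                         tau = 0.5, window_T = 24, ff_mult = 2,
                         decoder = c("pbd", "mlp"), no_gate = FALSE,
                         no_graph = FALSE, constrained = FALSE,
                         no_skip = FALSE) {
  decoder <- match.arg(decoder)
  if (d %% n_heads != 0) stopf("d (%d) must be divisible by n_heads (%d)", d, n_heads)
  if (tau <= 0) stopf("tau must be positive")
  structure(list(d = d, L = L, n_heads = n_heads, n_prompts = n_prompts,
                 tau = tau, window_T = window_T, ff_mult = ff_mult,
                 decoder = decoder, no_gate = no_gate, no_graph = no_graph,
                 constrained = constrained, no_skip = no_skip),
            class = "model_config")
}

resolve_layers <- function(config, N) config$L %||% (if (N <= 36) 2L else 4L)

#' Initialise all model parameters
#'
#' @param config A [model_config()].
#' @param N Number of series (fixes the layer count when `config$L` is NULL).
#' @param seed Optional seed for reproducible initialisation.
#' @return Nested parameter list (input/skip MLPs, missing-token `m`,
#'   transformer + SCA + layer norm per layer, decoder).
#' @export
init_model_params <- function(config, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- config$d
  L <- resolve_layers(config, N)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- list(skip_mlp = mlp2_init(1, d, d, scale1 = 1),
                        transformer = transformer_init(d, config$ff_mult),
                        sca = sca_params(d),
                        ln_out = ln_init(d))
  }
  dec <- if (config$decoder == "pbd") {
    list(prompts = matrix(rnorm(config$n_prompts * d), config$n_prompts, d),
         wq = lin_init(d, d), wk = lin_init(d, d), wv = lin_init(d, d),
         proj = lin_init(d, d), ln = ln_init(d), head = lin_init(1, d))
  } else {
    list(mlp = mlp2_init(d, d, 1))
  }
  list(input_mlp = mlp2_init(1, d, d, scale1 = 1), m = rnorm(d, sd = 0.02),
       layers = layers, decoder = dec)
}

#' Input projection: embed raw values, substitute the missing token
#'
#' `H0 = MLP(X) * M + m * (1 - M)` cellwise: observed cells get a learned
#' embedding of their value, missing cells all share the token `m`, so the
#' sentinel stored in masked cells of X can never influence the model.
#'
#' @param X N x T value matrix.
#' @param M Binary mask.
#' @param params Model parameters ([init_model_params()]).
#' @return N x T x d embedding array.
#' @export
input_project <- function(X, M, params) {
  N <- nrow(X); TT <- ncol(X)
  xv <- as.vector(t(X)); mv <- as.vector(t(M))   # time fastest
  H <- project_rows(xv, mv, params$input_mlp, params$m)
  unflatten_ntd(H, N, TT)
}

project_rows <- function(xv, mv, mlp, m_tok) {
  emb <- mlp2_fwd(matrix(xv, ncol = 1), mlp)$out
  emb * mv + outer(1 - mv, m_tok)
}

#' Skip projection: re-inject the raw input at each layer
#'
#' `H_skip = H_prev + MLP_l(X) * M + m * (1 - M)` with a layer-specific MLP
#' and the globally shared missing token; prevents gradient vanishing across
#' the encoder stack.
#'
#' @param H_prev N x T x d embeddings from the previous layer.
#' @param X,M Value matrix and mask.
#' @param params Model parameters.
#' @param layer Which layer's skip MLP to use.
#' @return N x T x d array.
#' @export
skip_project <- function(H_prev, X, M, params, layer = 1) {
  N <- nrow(X); TT <- ncol(X)
  xv <- as.vector(t(X)); mv <- as.vector(t(M))
  H <- flatten_ntd(H_prev) +
    project_rows(xv, mv, params$layers[[layer]]$skip_mlp, params$m)
  unflatten_ntd(H, N, TT)
}

#' Temporal transformer: per-series self-attention along time
#'
#' A post-norm transformer encoder layer applied independently to each
#' series (sinusoidal position encodings added first); no cross-series
#' mixing happens here.
#'
#' @param H_skip N x T x d array.
#' @param params Model parameters.
#' @param layer Layer index.
#' @param n_heads Attention heads.
#' @return N x T x d array.
#' @export
temporal_transform <- function(H_skip, params, layer = 1, n_heads = 4,
                               causal = FALSE) {
  N <- dim(H_skip)[1]; TT <- dim(H_skip)[2]; d <- dim(H_skip)[3]
  H <- flatten_ntd(H_skip)
  pe <- positional_encoding(TT, d)
  H <- H + pe[rep(seq_len(TT), N), ]
  f <- transformer_fwd(H, params$layers[[layer]]$transformer, block = TT,
                       nh = n_heads, causal = causal)
  unflatten_ntd(f$out, N, TT)
}

#' Run the full encoder
#'
#' Input projection, then per layer: skip projection, temporal transformer,
#' spatiotemporal causal attention, and residual layer normalisation.
#'
#' @param series An [st_series()].
#' @param params Model parameters.
#' @param config A [model_config()].
#' @param mode `"eval"` (deterministic hard gates) or `"train"`.
#' @return List: `H` (N x T x d final embeddings) and `gate_states`, one
#'   gate-state data frame per layer (each with a `layer` column).
#' @export
encode <- function(series, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  A <- if (config$no_graph) diag(1, nrow(series$X)) else series$A
  pairs <- sca_pairs(A, ncol(series$X), config$constrained)
  f <- model_fwd(params, config, as.vector(t(series$X)), as.vector(t(series$M)),
                 sca_pairs_batch(pairs, 1L), B = 1L, N = nrow(series$X),
                 TT = ncol(series$X), mode = mode)
  gs <- vector("list", length(f$layer_caches))
  for (l in seq_along(gs)) {
    g <- pair_frame(pairs)
    cl <- f$layer_caches[[l]]$sca$cache
    g$layer <- l
    g$rho <- if (is.null(cl$rho)) NA_real_ else cl$rho
    g$beta <- cl$beta
    g$alpha <- colMeans(cl$alphaT)
    gs[[l]] <- g[, c("layer", setdiff(names(g), "layer"))]
  }
  list(H = unflatten_ntd(f$H, nrow(series$X), ncol(series$X)), gate_states = gs)
}
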