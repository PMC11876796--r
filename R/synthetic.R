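#' Specification of a vector-autoregressive generator with a planted graph
#'
#' The generator draws stationary VAR(p) dynamics
#' `y[i,t] = sum_{j,l} coeffs[i,j,l] * y[j,t-l] + eps[i,t]`, so the planted
#' Granger graph is exactly the support of the coefficient tensor:
#' series j causes series i iff `coeffs[i,j,l] != 0` for some lag l.
#'
#' When `coeffs` is omitted, a random sparse coefficient tensor is drawn:
#' off-diagonal entries present with probability `density`, signs random,
#' diagonal lag-1 entries always present (self-persistence, as in real sensor
#' series), and the whole tensor rescaled so the companion-matrix spectral
#' radius equals `target_radius` (stationarity with visible autocorrelation).
#'
#' @param n_series Number of series N.
#' @param length Number of retained time steps T (after burn-in).
#' @param lag_order VAR order p.
#' @param coeffs Optional N x N x p array; `coeffs[i, j, l]` is the effect of
#'   series j at lag l on series i.
#' @param density Probability of an off-diagonal causal edge (used only when
#'   `coeffs` is drawn).
#' @param coef_sd Scale of drawn coefficients before radius rescaling.
#' @param target_radius Spectral radius the companion matrix is rescaled to.
#' @param noise_sd Innovation standard deviation.
#' @param burn_in Steps discarded before recording.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `var_spec`.
#' @export
var_spec <- function(n_series = 15, length = 480, lag_order = 1, coeffs = NULL,
                     density = 0.15, coef_sd = 0.4, target_radius = 0.75,
                     noise_sd = 1, burn_in = 100, seed = 1) {
  if (n_series < 1 || length < 1 || lag_order < 1) stopf("n_series, length, lag_order must be positive")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (burn_in < 100) burn_in <- 100
  if (is.null(coeffs)) {
    set.seed(child_seed(seed, "var-coeffs"))
    coeffs <- array(0, c(n_series, n_series, lag_order))
    for (l in seq_len(lag_order)) {
      pick <- matrix(runif(n_series^2) < density, n_series)
      diag(pick) <- FALSE
      vals <- matrix(rnorm(n_series^2, sd = coef_sd) *
                       sample(c(-1, 1), n_series^2, TRUE), n_series)
      coeffs[, , l] <- pick * abs(vals) * sign(vals)
    }
    diag(coeffs[, , 1]) <- runif(n_series, 0.3, 0.6)
    sr <- companion_radius(coeffs)
    if (sr > 0) coeffs <- coeffs * (target_radius / sr)^(1 / 1)
    # per-lag geometric rescale keeps the support; re-check radius
    for (k in 1:20) {
      sr <- companion_radius(coeffs)
      if (abs(sr - target_radius) < 1e-6 || sr == 0) break
      coeffs <- coeffs * (target_radius / sr)
    }
  }
  coeffs <- unname(coeffs)
  if (length(dim(coeffs)) == 2) coeffs <- array(coeffs, c(dim(coeffs), 1))
  structure(list(n_series = n_series, length = length, lag_order = dim(coeffs)[3],
                 coeffs = coeffs, noise_sd = noise_sd, burn_in = burn_in,
                 seed = seed),
            class = "var_spec")
}

companion_radius <- function(coeffs) {
  N <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  C <- matrix(0, N * p, N * p)
  for (l in seq_len(p)) C[1:N, ((l - 1) * N + 1):(l * N)] <- coeffs[, , l]
  if (p > 1) C[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(1, N * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a stationary VAR with a planted Granger graph
#'
#' @param spec A [var_spec()].
#' @return List with `Y` (complete N x T matrix), `G_true` (binary N x N;
#'   `G_true[j, i] = 1` means series j Granger-causes series i) and the
#'   generating [var_spec()].
#' @export
simulate_var <- function(spec) {
  sr <- companion_radius(spec$coeffs)
  if (sr >= 1)
    stopf("non-stationary VAR: companion spectral radius %.3f >= 1", sr)
  N <- spec$n_series; TT <- spec$length; p <- spec$lag_order
  set.seed(child_seed(spec$seed, "var-noise"))
  total <- TT + spec$burn_in
  Y <- matrix(0, N, total + p)
  eps <- matrix(rnorm(N * total, sd = spec$noise_sd), N, total)
  for (t in seq_len(total)) {
    acc <- eps[, t]
    for (l in seq_len(p)) acc <- acc + spec$coeffs[, , l] %*% Y[, p + t - l]
    Y[, p + t] <- acc
  }
  Y <- Y[, (p + spec$burn_in + 1):(p + total), drop = FALSE]
  G_true <- matrix(0, N, N)
  for (l in seq_len(p)) G_true <- G_true + (spec$coeffs[, , l] != 0)
  G_true <- t((G_true > 0) * 1)   # [source j, target i]
  diag(G_true) <- 0
  list(Y = Y, G_true = G_true, spec = spec)
}

#' Contaminate a series with confounders
#'
#' Adds the two confounders that plague distance-built sensor networks: a
#' shared latent background process (an AR(1) with coefficient 0.5, scaled by
#' `background_sd`, added to every series — temporally correlated common
#' noise), and `n_shortcuts` non-causal shortcut edges inserted into the
#' adjacency between node pairs with no planted causal link in either
#' direction.
#'
#' @param Y Complete N x T value matrix.
#' @param A Adjacency matrix to receive shortcut edges.
#' @param G_true Binary planted graph (source x target), used to keep
#'   shortcuts disjoint from real causal edges.
#' @param background_sd Standard deviation of the shared background process
#'   (0 disables it).
#' @param n_shortcuts Number of undirected shortcut edges to add.
#' @param seed Integer seed.
#' @return List with contaminated `Y`, updated `A`, and `shortcut_edges`
#'   (two-column matrix of node indices, one row per added undirected edge).
#' @export
inject_confounders <- function(Y, A, G_true, background_sd = 1, n_shortcuts = 5,
                               seed = 1) {
  if (background_sd < 0) stopf("background_sd must be nonnegative")
  N <- nrow(Y); TT <- ncol(Y)
  set.seed(child_seed(seed, "confound"))
  if (background_sd > 0) {
    z <- numeric(TT)
    z[1] <- rnorm(1)
    for (t in 2:TT) z[t] <- 0.5 * z[t - 1] + rnorm(1)
    z <- z / sd(z) * background_sd
    Y <- Y + matrix(z, N, TT, byrow = TRUE)
  }
  shortcut_edges <- matrix(integer(0), 0, 2)
  if (n_shortcuts > 0) {
    cand <- which(upper.tri(G_true) & G_true == 0 & t(G_true) == 0 &
                    A == 0 & t(A) == 0, arr.ind = TRUE)
    if (nrow(cand) < n_shortcuts)
      stopf("requested %d shortcuts but only %d non-causal non-edges available",
            n_shortcuts, nrow(cand))
    pick <- cand[sample(nrow(cand), n_shortcuts), , drop = FALSE]
    for (r in seq_len(n_shortcuts)) {
      A[pick[r, 1], pick[r, 2]] <- 1
      A[pick[r, 2], pick[r, 1]] <- 1
    }
    shortcut_edges <- unname(pick)
  }
  list(Y = Y, A = A, shortcut_edges = shortcut_edges)
}

#' Missingness specification
#'
#' Point missing masks each cell independently; block missing masks
#' contiguous temporal runs per node plus whole-node spans (sensor outages).
#' Defaults follow the standard benchmark protocol: 25% point missing, 5%
#' spatial and 0.15% temporal block rates with block lengths of 2-8 steps
#' (the benchmark's 1-4 hours of 5-minute data scaled to short series).
#'
#' @param mode `"point"` or `"block"`.
#' @param point_rate Probability a cell is masked in point mode.
#' @param block_spatial_rate Per-node-per-window probability of a whole-node
#'   outage span.
#' @param block_temporal_rate Per-cell probability that a temporal block
#'   starts there.
#' @param block_len_range Integer (min, max) block length in steps.
#' @param seed Integer seed.
#' @return A list of class `missing_spec`.
#' @export
missing_spec <- function(mode = c("point", "block"), point_rate = 0.25,
                         block_spatial_rate = 0.05, block_temporal_rate = 0.0015,
                         block_len_range = c(2L, 8L), seed = 1) {
  mode <- match.arg(mode)
  for (r in c(point_rate, block_spatial_rate, block_temporal_rate))
    if (r < 0 || r > 1) stopf("rates must be in [0, 1]")
  if (block_len_range[1] < 1 || block_len_range[1] > block_len_range[2])
    stopf("block_len_range must satisfy 1 <= min <= max")
  structure(list(mode = mode, point_rate = point_rate,
                 block_spatial_rate = block_spatial_rate,
                 block_temporal_rate = block_temporal_rate,
                 block_len_range = as.integer(block_len_range), seed = seed),
            class = "missing_spec")
}

#' Apply a missingness pattern and produce an evaluation mask
#'
#' Masks cells of a series according to `spec` and records which cells were
#' observed before but hidden now — the evaluation mask on which imputation
#' error is scored (ground truth is known exactly for those cells).  Never
#' unmasks: the output mask is elementwise `<=` the input mask.
#'
#' @param s An [st_series()] (typically fully observed).
#' @param spec A [missing_spec()].
#' @return List with the masked `series` and binary `eval_mask` (N x T).
#' @export
apply_missing <- function(s, spec) {
  N <- nrow(s$X); TT <- ncol(s$X)
  set.seed(child_seed(spec$seed, paste0("missing-", spec$mode)))
  hide <- matrix(0, N, TT)
  if (spec$mode == "point") {
    hide <- matrix(runif(N * TT) < spec$point_rate, N, TT) * 1
  } else {
    lens <- spec$block_len_range
    for (i in seq_len(N)) {
      starts <- which(runif(TT) < spec$block_temporal_rate)
      for (st in starts) {
        len <- sample(lens[1]:lens[2], 1)
        hide[i, st:min(TT, st + len - 1)] <- 1
      }
    }
    outage <- which(runif(N) < spec$block_spatial_rate)
    for (i in outage) {
      len <- sample(lens[1]:lens[2], 1) * 3L  # outages run longer than glitches
      st <- sample(max(1, TT - len + 1), 1)
      hide[i, st:min(TT, st + len - 1)] <- 1
    }
  }
  eval_mask <- hide * s$M
  M_new <- s$M * (1 - hide)
  series <- st_series(s$X * M_new, s$A, M_new,
                      node_ids = s$node_ids, time_index = s$time_index)
  list(series = series, eval_mask = eval_mask)
}

#' Per-batch artificial masking for self-supervised training
#'
#' For each training batch, a masking rate p is drawn uniformly from `rates`
#' and a fraction p of the *currently observed* cells is hidden; those cells
#' become the loss targets for the batch.  Cells missing in the input are
#' never loss targets (their truth is unknown).
#'
#' @param M Binary observation mask (any shape; applied elementwise).
#' @param rates Candidate masking rates, each in (0, 1).
#' @param seed Optional seed; omit to use the ambient RNG stream inside a
#'   training loop.
#' @return List with `M_input` (mask the model sees), `loss_mask` (cells to
#'   score), and the drawn `p`.
#' @export
training_mask_sampler <- function(M, rates = c(0.2, 0.5, 0.8), seed = NULL) {
  if (length(rates) == 0 || any(rates <= 0) || any(rates >= 1))
    stopf("rates must be nonempty, each in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- rates[sample.int(length(rates), 1)]
  hide <- (array(runif(length(M)), dim(M)) < p) * M
  list(M_input = M * (1 - hide), loss_mask = hide, p = p)
}

#' Generate the package's reference synthetic study set
#'
#' One call producing everything downstream stages need: a stationary sparse
#' VAR with a planted Granger graph, adjacency equal to the (symmetrised)
#' planted graph plus self-loops, confounder contamination (shared AR(1)
#' background noise and non-causal shortcut edges), and a point-missing
#' evaluation mask.  Defaults are the package's reference conditions for
#' desk-scale experiments: 15 series, 20 windows of 24 steps, planted edge
#' density 0.15, 5 shortcut edges, unit background noise, 25% point missing.
#'
#' @param n_series,n_windows,window_T Problem size (total length is
#'   `n_windows * window_T`).
#' @param density Planted edge density.
#' @param n_shortcuts Non-causal shortcut edges added to the adjacency.
#' @param background_sd Shared background noise scale.
#' @param point_rate Evaluation missingness rate.
#' @param seed Integer seed controlling every stage.
#' @return List: `series` (masked [st_series()]), `Y` (complete values),
#'   `G_true`, `shortcut_edges`, `eval_mask`, and the component specs.
#' @export
synthetic_dataset <- function(n_series = 15, n_windows = 20, window_T = 24,
                              density = 0.15, n_shortcuts = 5,
                              background_sd = 1, point_rate = 0.25, seed = 1) {
  vs <- var_spec(n_series = n_series, length = n_windows * window_T,
                 density = density, seed = seed)
  sim <- simulate_var(vs)
  A <- ((sim$G_true + t(sim$G_true)) > 0) * 1
  diag(A) <- 1
  conf <- inject_confounders(sim$Y, A, sim$G_true,
                             background_sd = background_sd,
                             n_shortcuts = n_shortcuts, seed = seed)
  full <- st_series(conf$Y, conf$A)
  ms <- missing_spec("point", point_rate = point_rate, seed = seed)
  am <- apply_missing(full, ms)
  list(series = am$series, Y = conf$Y, G_true = sim$G_true,
       shortcut_edges = conf$shortcut_edges, eval_mask = am$eval_mask,
       var_spec = vs, missing_spec = ms, window_T = window_T)
}
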