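#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 8e-4 with a
#' cosine schedule, at most 300 epochs with early-stopping patience 40,
#' batch size 8, per-batch artificial masking rates {0.2, 0.5, 0.8}, and an
#' l1 coefficient of 0.001 on the causal-gate probabilities.
#'
#' @param lambda_l1 Nonnegative l1 coefficient on gate probabilities; the
#'   penalty is `lambda_l1 * mean(rho)` over all gates of the forward pass,
#'   making it batch- and graph-size invariant.
#' @param lr Initial Adam learning rate.
#' @param max_epochs,patience Epoch budget and early-stopping patience
#'   (epochs without validation improvement).
#' @param batch_size Windows per batch.
#' @param training_rates Candidate per-batch artificial masking rates.
#' @param val_frac Fraction of windows held out for validation (at least 1).
#' @param stride Offset between consecutive training windows; defaults to
#'   the window length (non-overlapping).  Smaller strides give more
#'   optimiser steps per epoch from the same series; validation windows are
#'   always drawn from the non-overlapping grid and any training window
#'   overlapping one is dropped.
#' @param gate_warmup Number of initial epochs trained with every causal
#'   gate forced open (no gate parameters updated, no l1 term).  Lets the
#'   attention and message paths become informative before the gate
#'   dynamics decide which pairs to prune; 0 disables.
#' @param lambda_ramp `"none"` applies `lambda_l1` from the first gated
#'   epoch; `"quadratic"` scales it by
#'   `((epoch - warmup)/(ramp_horizon - warmup))^2` so sparsity pressure
#'   peaks once the message paths are trained and gates commit by the
#'   gradient-threshold dynamics instead of collapsing while messages are
#'   still uninformative.
#' @param ramp_horizon Epoch at which a quadratic ramp reaches the full
#'   `lambda_l1`; defaults to `max_epochs`.  Budget-truncated runs can keep
#'   the reference schedule (e.g. 300) so that they apply only the early
#'   part of the ramp.
#' @param gate_lr_scale Multiplier (< 1 slows) on the update size of the
#'   gate-scorer parameters.  The gate-convergence analysis treats the rest
#'   of the network as fixed while each rho evolves; a smaller scale
#'   enforces that separation of timescales, preventing the gates from
#'   closing en masse before the attention and message paths are trained.
#' @param seed Integer seed for initialisation, shuffling, masking, Gumbel
#'   draws.
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda_l1 = 0.001, lr = 8e-4, max_epochs = 300,
                         patience = 40, batch_size = 8,
                         training_rates = c(0.2, 0.5, 0.8), val_frac = 0.1,
                         stride = NULL, gate_warmup = 0,
                         lambda_ramp = c("none", "quadratic"),
                         ramp_horizon = NULL, gate_lr_scale = 1, seed = 1,
                         verbose = FALSE) {
  lambda_ramp <- match.arg(lambda_ramp)
  if (lambda_l1 < 0) stopf("lambda_l1 must be nonnegative")
  if (lr <= 0 || max_epochs < 1 || batch_size < 1) stopf("invalid training config")
  if (patience > max_epochs) patience <- max_epochs
  structure(list(lambda_l1 = lambda_l1, lr = lr, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 training_rates = training_rates, val_frac = val_frac,
                 stride = stride, gate_warmup = gate_warmup,
                 lambda_ramp = lambda_ramp, ramp_horizon = ramp_horizon,
                 gate_lr_scale = gate_lr_scale, seed = seed,
                 verbose = verbose),
            class = "train_config")
}

#' Masked mean-absolute-error loss with gate sparsity penalty
#'
#' `loss = sum(mask * |Y - Yhat|) / max(sum(mask), 1) +
#' lambda_l1 * mean(rho)`: the imputation error over loss-target cells plus
#' the l1 pressure that drives gate probabilities to commit to 0 or 1.
#'
#' @param Y,Yhat Ground-truth and predicted matrices (same shape).
#' @param loss_mask Binary matrix of cells to score.
#' @param rho_values Gate probabilities from the forward pass (vector or
#'   list of vectors); may be NULL.
#' @param lambda_l1 Penalty coefficient.
#' @param penalty `"mean"` averages the penalty over gates (the default
#'   contract); `"per_target"` divides the summed penalty by the number of
#'   loss targets instead, which keeps each gate's l1 pressure on the same
#'   scale as each cell's error gradient — the calibration under which
#'   `lambda_l1 = 0.001` reproduces the reference gradient-threshold
#'   dynamics (training uses this form).
#' @return Scalar loss.
#' @export
masked_mae_loss <- function(Y, Yhat, loss_mask, rho_values = NULL,
                            lambda_l1 = 0, penalty = c("mean", "per_target")) {
  penalty <- match.arg(penalty)
  n <- sum(loss_mask)
  if (n == 0) warning("empty loss mask: data term is 0")
  data_term <- sum(loss_mask * abs(Y - Yhat)) / max(n, 1)
  rho <- unlist(rho_values, use.names = FALSE)
  pen <- if (lambda_l1 > 0 && length(rho) > 0) {
    if (penalty == "mean") lambda_l1 * mean(abs(rho))
    else lambda_l1 * sum(abs(rho)) / max(n, 1)
  } else 0
  data_term + pen
}

window_starts <- function(TT, window_T) {
  if (TT < window_T) stopf("series length %d shorter than window %d", TT, window_T)
  seq(1, TT - window_T + 1, by = window_T)
}

#' Train the imputation network
#'
#' Self-supervised training: each batch hides a random fraction
#' p in `training_rates` of the currently observed cells and is scored on
#' recovering exactly those cells (originally missing cells are never loss
#' targets).  Optimised with Adam under a cosine learning-rate schedule;
#' early stopping tracks masked MAE on a held-out set of windows whose
#' artificial mask is drawn once (p = 0.5) and fixed across epochs.  Values
#' are standardised by the observed training mean/sd; the scaler is stored
#' in the checkpoint.
#'
#' @param series An [st_series()] with missing cells.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @return List of class `st_model`: trained parameters at the best
#'   validation epoch, the configs, scaler, and a `report` (class
#'   `training_report`) with per-epoch train/validation loss, learning rate
#'   and the fraction of gate probabilities already committed (outside
#'   (0.1, 0.9)).
#' @export
train_imputer <- function(series, config = model_config(), tc = train_config()) {
  set.seed(child_seed(tc$seed, "train"))
  N <- nrow(series$X); TT <- ncol(series$X)
  wT <- config$window_T
  A <- if (config$no_graph) diag(1, N) else series$A
  pairs1 <- sca_pairs(A, wT, config$constrained)
  mu <- sum(series$X * series$M) / max(1, sum(series$M))
  sdv <- sqrt(sum(series$M * (series$X - mu)^2) / max(1, sum(series$M) - 1))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  Xs <- (series$X - mu) / sdv * series$M
  grid <- window_starts(TT, wT)
  stride <- tc$stride %||% wT
  starts_all <- seq(1, TT - wT + 1, by = stride)
  n_val <- max(1L, round(tc$val_frac * length(grid)))
  val_starts <- sort(sample(grid, n_val))
  overlaps_val <- vapply(starts_all, function(s)
    any(s < val_starts + wT & val_starts < s + wT), TRUE)
  starts <- c(starts_all[!overlaps_val], val_starts)
  train_idx <- seq_len(sum(!overlaps_val))
  val_idx <- sum(!overlaps_val) + seq_along(val_starts)
  ## degenerate series (a single window): train on the validation windows
  if (length(train_idx) == 0) train_idx <- val_idx
  win_X <- lapply(starts, function(s) Xs[, s:(s + wT - 1), drop = FALSE])
  win_M <- lapply(starts, function(s) series$M[, s:(s + wT - 1), drop = FALSE])
  ## fixed validation artificial mask
  val_masks <- lapply(val_idx, function(w) training_mask_sampler(win_M[[w]], 0.5))
  params <- init_model_params(config, N, seed = child_seed(tc$seed, "init"))
  opt <- adam_init(params)
  best <- list(val = Inf, epoch = 0L, params = params)
  hist <- data.frame(epoch = integer(0), lr = numeric(0), train_loss = numeric(0),
                     val_loss = numeric(0), rho_converged = numeric(0))
  for (epoch in seq_len(tc$max_epochs)) {
    lr <- cosine_lr(epoch, tc$max_epochs, tc$lr)
    ep_config <- config
    warm <- tc$gate_warmup %||% 0
    if (epoch <= warm) ep_config$no_gate <- TRUE
    horizon <- tc$ramp_horizon %||% tc$max_epochs
    lam_ep <- if (identical(tc$lambda_ramp, "quadratic"))
      tc$lambda_l1 * max(0, (epoch - warm) / max(1, horizon - warm))^2
    else tc$lambda_l1
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    ep_loss <- 0; ep_n <- 0; rho_conv <- c()
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      masks <- training_mask_sampler(
        do.call(rbind, lapply(win_M[idx], function(m) matrix(as.vector(t(m)), 1))),
        tc$training_rates)
      xv_full <- unlist(lapply(win_X[idx], function(x) as.vector(t(x))))
      mv_in <- as.vector(t(masks$M_input))
      lm <- as.vector(t(masks$loss_mask))
      xv_in <- xv_full * mv_in
      fwd <- model_fwd(params, ep_config, xv_in, mv_in,
                       sca_pairs_batch(pairs1, B), B, N, wT, mode = "train")
      if (any(!is.finite(fwd$yhat)))
        stopf("divergent loss (non-finite predictions) in epoch %d batch %d", epoch, bi)
      n_t <- max(sum(lm), 1)
      loss <- masked_mae_loss(xv_full, fwd$yhat, lm, fwd$rho_list, lam_ep,
                              penalty = "per_target")
      gy <- -lm * sign(xv_full - fwd$yhat) / n_t
      n_rho <- sum(vapply(fwd$rho_list, function(r) length(r %||% numeric(0)), 0))
      grads <- model_bwd(params, ep_config, fwd, gy,
                         lambda_l1 = if (n_rho > 0) lam_ep * n_rho / n_t else 0)
      st <- adam_step(params, grads, opt, lr)
      gsc <- tc$gate_lr_scale %||% 1
      if (gsc != 1) {
        for (l in seq_along(st$params$layers)) {
          for (nm in c("Wqc", "Wkc", "wc1", "wc2", "bc")) {
            old <- params$layers[[l]]$sca[[nm]]
            st$params$layers[[l]]$sca[[nm]] <-
              old + gsc * (st$params$layers[[l]]$sca[[nm]] - old)
          }
        }
      }
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      rr <- unlist(fwd$rho_list, use.names = FALSE)
      if (length(rr) > 0) rho_conv <- c(rho_conv, rho_convergence_fraction(rr))
    }
    val_loss <- validation_loss(params, config, win_X, val_idx, val_masks,
                                pairs1, N, wT)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss / ep_n,
                                   val_loss = val_loss,
                                   rho_converged = if (length(rho_conv)) mean(rho_conv) else NA_real_))
    if (tc$verbose)
      message(sprintf("epoch %3d lr %.5f train %.4f val %.4f rho-conv %.2f",
                      epoch, lr, ep_loss / ep_n, val_loss,
                      tail(hist$rho_converged, 1)))
    if (val_loss < best$val) {
      best <- list(val = val_loss, epoch = epoch, params = params)
    } else if (epoch - best$epoch >= tc$patience) break
  }
  report <- structure(list(history = hist, best_epoch = best$epoch,
                           best_val = best$val,
                           stopped_epoch = nrow(hist)),
                      class = "training_report")
  structure(list(version = 1L, config = config, train_config = tc,
                 params = best$params, scaler = list(mu = mu, sd = sdv),
                 n_series = N, report = report),
            class = "st_model")
}

validation_loss <- function(params, config, win_X, val_idx, val_masks,
                            pairs1, N, wT) {
  tot <- 0; n <- 0
  for (k in seq_along(val_idx)) {
    w <- val_idx[k]
    vm <- val_masks[[k]]
    xv_full <- as.vector(t(win_X[[w]]))
    mv <- as.vector(t(vm$M_input))
    lm <- as.vector(t(vm$loss_mask))
    fwd <- model_fwd(params, config, xv_full * mv, mv,
                     sca_pairs_batch(pairs1, 1L), 1L, N, wT, mode = "eval")
    tot <- tot + sum(lm * abs(xv_full - fwd$yhat))
    n <- n + sum(lm)
  }
  tot / max(n, 1)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("<training_report> %d epochs (best %d, val MAE %.4f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val))
  invisible(x)
}

#' @export
print.st_model <- function(x, ...) {
  cat(sprintf("<st_model> d=%d L=%d decoder=%s; trained %d epochs (best %d)\n",
              x$config$d, length(x$params$layers), x$config$decoder,
              x$report$stopped_epoch, x$report$best_epoch))
  invisible(x)
}

#' Impute missing values with a trained model
#'
#' Runs the network in deterministic evaluation mode (hard causal gates)
#' over consecutive windows and fills only the missing cells:
#' `output = M * X + (1 - M) * Yhat`.  Observed values pass through
#' untouched; repeated calls give identical output.
#'
#' @param model An `st_model` from [train_imputer()].
#' @param series An [st_series()] with the same number of series the model
#'   was trained on.
#' @param stride Offset between inference windows; the default half-window
#'   overlap centres most cells in at least one window, and overlapping
#'   predictions are averaged.  Use `stride = model$config$window_T` for
#'   disjoint windows.
#' @return N x T matrix of completed values.
#' @export
impute <- function(model, series, stride = NULL) {
  N <- nrow(series$X); TT <- ncol(series$X)
  if (N != model$n_series)
    stopf("series has %d rows but the model was trained on %d", N, model$n_series)
  config <- model$config
  wT <- config$window_T
  stride <- stride %||% max(1L, wT %/% 2L)
  A <- if (config$no_graph) diag(1, N) else series$A
  pairs1 <- sca_pairs(A, wT, config$constrained)
  Xs <- (series$X - model$scaler$mu) / model$scaler$sd * series$M
  starts <- unique(c(seq(1, TT - wT + 1, by = stride), TT - wT + 1))
  Yhat <- matrix(0, N, TT)
  wsum <- matrix(0, N, TT)
  for (s in starts) {
    cols <- s:(s + wT - 1)
    xv <- as.vector(t(Xs[, cols, drop = FALSE]))
    mv <- as.vector(t(series$M[, cols, drop = FALSE]))
    fwd <- model_fwd(model$params, config, xv, mv,
                     sca_pairs_batch(pairs1, 1L), 1L, N, wT, mode = "eval")
    Yhat[, cols] <- Yhat[, cols, drop = FALSE] + matrix(fwd$yhat, N, wT, byrow = TRUE)
    wsum[, cols] <- wsum[, cols, drop = FALSE] + 1
  }
  Yhat <- (Yhat / wsum) * model$scaler$sd + model$scaler$mu
  series$M * series$X + (1 - series$M) * Yhat
}

#' Column-mean and last-observation-carried-forward baseline imputers
#'
#' `impute_column_mean` fills a missing cell with the mean of the observed
#' values at the same time step across series (falling back to the series
#' mean, then the global mean).  `impute_locf` carries the last observed
#' value of the series forward (backfilling leading gaps with the first
#' observation, all-missing series with the global mean).
#'
#' @param series An [st_series()].
#' @return N x T completed matrix.
#' @export
impute_column_mean <- function(series) {
  X <- series$X; M <- series$M
  glob <- sum(X * M) / max(1, sum(M))
  colmean <- colSums(X * M) / pmax(1, colSums(M))
  colmean[colSums(M) == 0] <- glob
  rowmean <- rowSums(X * M) / pmax(1, rowSums(M))
  rowmean[rowSums(M) == 0] <- glob
  fill <- matrix(colmean, nrow(X), ncol(X), byrow = TRUE)
  M * X + (1 - M) * fill
}

#' @rdname impute_column_mean
#' @export
impute_locf <- function(series) {
  X <- series$X; M <- series$M
  glob <- sum(X * M) / max(1, sum(M))
  out <- X
  for (i in seq_len(nrow(X))) {
    obs <- which(M[i, ] == 1)
    if (length(obs) == 0) { out[i, ] <- glob; next }
    last <- X[i, obs[1]]   # backfill leading gap with first observation
    for (t in seq_len(ncol(X))) {
      if (M[i, t] == 1) last <- X[i, t] else out[i, t] <- last
    }
  }
  out
}

#' Score an imputation on an evaluation mask
#'
#' @param Yhat Completed matrix.
#' @param Y Ground-truth complete matrix.
#' @param eval_mask Binary matrix of scored cells.
#' @return List with `mae` and `mse` over the masked cells.
#' @export
evaluate_imputation <- function(Yhat, Y, eval_mask) {
  n <- max(1, sum(eval_mask))
  list(mae = sum(eval_mask * abs(Y - Yhat)) / n,
       mse = sum(eval_mask * (Y - Yhat)^2) / n)
}
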