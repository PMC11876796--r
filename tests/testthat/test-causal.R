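test_that("the gate-convergence fraction counts committed probabilities", {
  expect_equal(rho_convergence_fraction(rep(0.05, 7)), 1)
  expect_equal(rho_convergence_fraction(rep(0.5, 7)), 0)
  expect_equal(rho_convergence_fraction(c(0.05, 0.5, 0.95, 0.99)), 0.75)
  expect_error(rho_convergence_fraction(numeric(0)), "rho")
  # widening the thresholds toward the middle never decreases the fraction
  set.seed(80)
  rho <- runif(500)
  f1 <- rho_convergence_fraction(rho, 0.1, 0.9)
  f2 <- rho_convergence_fraction(rho, 0.2, 0.8)
  f3 <- rho_convergence_fraction(rho, 0.4, 0.6)
  expect_true(f1 <= f2 && f2 <= f3)
})

test_that("rank AUC matches enumeration and handles ties by midrank", {
  W <- matrix(c(0, 0.9, 0.1,
                0.8, 0, 0.2,
                0.3, 0.4, 0), 3, byrow = TRUE)
  truth <- matrix(c(0, 1, 0,
                    1, 0, 0,
                    0, 1, 0), 3, byrow = TRUE)
  g <- causal_graph(W, truth)
  # enumeration oracle over all (positive, negative) pairs
  off <- !diag(TRUE, 3)
  pos <- W[off][truth[off] == 1]; neg <- W[off][truth[off] == 0]
  ref <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(auc_causal(g), ref)
  # perfect ranking and constant scores
  Wp <- truth * 0.5 + 0.1
  expect_equal(auc_causal(causal_graph(Wp, truth)), 1)
  expect_equal(auc_causal(causal_graph(matrix(0.3, 3, 3), truth)), 0.5)
  expect_error(auc_causal(causal_graph(W, matrix(0, 3, 3))), "positives")
  expect_error(auc_causal(causal_graph(W)), "truth")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(81)
  N <- 8
  W <- matrix(runif(N * N), N)
  truth <- matrix(rbinom(N * N, 1, 0.3), N)
  diag(truth) <- 0
  off <- !diag(TRUE, N)
  if (sum(truth[off]) %in% c(0, sum(off))) skip("degenerate truth draw")
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth[off], W[off], direction = "<"))))
  expect_equal(auc_causal(causal_graph(W, truth)), ref, tolerance = 1e-10)
})

test_that("causal-matrix extraction matches a brute-force pooling oracle", {
  set.seed(82)
  data <- synthetic_dataset(seed = 7, n_series = 4, n_windows = 2, window_T = 6,
                            n_shortcuts = 1)
  config <- model_config(d = 8, L = 1, n_heads = 2, n_prompts = 4, window_T = 6)
  tc <- train_config(max_epochs = 2, patience = 2, batch_size = 2, seed = 7)
  m <- train_imputer(data$series, config, tc)
  graph <- extract_causal_matrix(m, data$series)
  # recompute from the exported per-window gate states with four plain loops
  N <- 4; TT <- 6
  starts <- seq(1, 12, by = 6)
  Wref <- matrix(0, N, N)
  for (s0 in starts) {
    sub <- st_series(data$series$X[, s0:(s0 + 5)], data$series$A,
                     data$series$M[, s0:(s0 + 5)])
    sub$X <- (sub$X - m$scaler$mu) / m$scaler$sd * sub$M
    enc <- encode(sub, m$params, m$config, mode = "eval")
    Wref <- Wref + oracle_causal_matrix(enc$gate_states[[1]], N, TT)
  }
  Wref <- Wref / length(starts)
  expect_equal(graph$W, Wref, tolerance = 1e-10)
  expect_true(all(graph$W >= 0 & graph$W <= 1 / TT^2 + 1e-12))
  # rho values for convergence statistics come along
  expect_gt(length(graph$meta$rho_values), 0)
  expect_true(all(graph$meta$rho_values > 0 & graph$meta$rho_values < 1))
})

test_that("degenerate gate settings give the expected extreme matrices", {
  set.seed(83)
  data <- synthetic_dataset(seed = 8, n_series = 4, n_windows = 1, window_T = 6,
                            n_shortcuts = 1)
  config <- model_config(d = 8, L = 1, n_heads = 2, n_prompts = 4, window_T = 6)
  tc <- train_config(max_epochs = 1, patience = 1, batch_size = 1, seed = 8)
  m <- train_imputer(data$series, config, tc)
  # all gates closed -> zero matrix
  m0 <- m; m0$params$layers[[1]]$sca$bc <- -100
  g0 <- extract_causal_matrix(m0, data$series)
  expect_true(all(g0$W == 0))
  # all gates open -> every graph edge at the 1/T^2 ceiling
  m1 <- m; m1$params$layers[[1]]$sca$bc <- 100
  g1 <- extract_causal_matrix(m1, data$series)
  expect_equal(g1$W[data$series$A != 0], rep(1 / 36, sum(data$series$A != 0)))
  expect_true(all(g1$W[data$series$A == 0] == 0))
})

test_that("the gate-dynamics oracle converges by the sign of g - lambda", {
  set.seed(84)
  h <- rnorm(8)
  # g > lambda drives rho to 1
  up <- theorem1_oracle(theorem1_config(lambda_l1 = 1e-3, dyhat_dhout = 1,
                                        alpha = 0.5, Z = 1, v = 4e-3,
                                        h_in = h, eta = 2, n_steps = 60000))
  expect_gt(tail(up, 1), 0.99)
  # g < lambda drives rho to 0
  dn <- theorem1_oracle(theorem1_config(lambda_l1 = 1e-3, dyhat_dhout = 1,
                                        alpha = 0.5, Z = 1, v = 1e-3,
                                        h_in = h, eta = 2, n_steps = 60000))
  expect_lt(tail(dn, 1), 0.01)
  # g = lambda is stationary
  flat <- theorem1_oracle(theorem1_config(lambda_l1 = 1e-3, dyhat_dhout = 1,
                                          alpha = 1, Z = 1, v = 1e-3,
                                          h_in = h, n_steps = 50))
  expect_equal(var(flat), 0)
  # zero embeddings cannot move and are flagged
  frozen <- theorem1_oracle(theorem1_config(h_in = rep(0, 4), n_steps = 10))
  expect_true(attr(frozen, "stationary"))
  expect_equal(var(frozen), 0)
})

test_that("the oracle limit is a pure sign function of g - lambda over a grid", {
  set.seed(85)
  for (lambda in c(1e-3, 1e-2)) {
    for (mult in c(0.25, 0.5, 2, 4)) {
      h <- rnorm(6)
      # choose v so that g = mult * lambda with alpha/Z = 0.5
      cfg <- theorem1_config(lambda_l1 = lambda, dyhat_dhout = 1, alpha = 0.5,
                             Z = 1, v = 2 * mult * lambda, h_in = h,
                             eta = 0.5 / lambda / 100, n_steps = 40000)
      traj <- theorem1_oracle(cfg)
      if (mult > 1) expect_gt(tail(traj, 1), 0.99) else
        expect_lt(tail(traj, 1), 0.01)
    }
  }
})
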