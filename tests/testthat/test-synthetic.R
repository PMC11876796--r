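test_that("VAR recursion is exact for a hand-computable two-series system", {
  # series 2 depends only on series 1 at lag 1 with coefficient 0.9;
  # series 1 is white noise
  coeffs <- array(0, c(2, 2, 1))
  coeffs[2, 1, 1] <- 0.9
  spec <- var_spec(n_series = 2, length = 50, coeffs = coeffs,
                   noise_sd = 1e-8, seed = 4)
  sim <- simulate_var(spec)
  expect_equal(sim$G_true, matrix(c(0, 0, 1, 0), 2),
               ignore_attr = TRUE)   # 1 -> 2 only
  # direct recursion oracle: y2[t] = 0.9 * y1[t-1] up to the tiny noise
  expect_lt(max(abs(sim$Y[2, 2:50] - 0.9 * sim$Y[1, 1:49])), 1e-6)
})

test_that("zero coefficients give white noise and an empty planted graph", {
  spec <- var_spec(n_series = 3, length = 400,
                   coeffs = array(0, c(3, 3, 1)), seed = 5)
  sim <- simulate_var(spec)
  expect_equal(sim$G_true, matrix(0, 3, 3))
  # white noise: lag-1 autocorrelation near zero
  ac <- cor(sim$Y[1, -1], sim$Y[1, -400])
  expect_lt(abs(ac), 0.15)
})

test_that("VAR(1) moments match the Yule-Walker prediction", {
  A1 <- matrix(c(0.6, 0.2, 0, 0.5), 2, byrow = TRUE)
  spec <- var_spec(n_series = 2, length = 20000,
                   coeffs = array(A1, c(2, 2, 1)), noise_sd = 1, seed = 6)
  sim <- simulate_var(spec)
  # solve the discrete Lyapunov equation for the stationary covariance
  S <- diag(2)
  for (k in 1:300) S <- A1 %*% S %*% t(A1) + diag(2)
  G1 <- A1 %*% S   # lag-1 autocovariance E[y_t y_{t-1}'] = A S
  emp_S <- tcrossprod(sim$Y) / ncol(sim$Y)
  emp_G1 <- sim$Y[, -1] %*% t(sim$Y[, -ncol(sim$Y)]) / (ncol(sim$Y) - 1)
  expect_lt(max(abs(emp_S - S)), 0.15)
  expect_lt(max(abs(emp_G1 - G1)), 0.15)
})

test_that("simulation is reproducible and rejects unstable systems", {
  s1 <- simulate_var(var_spec(seed = 7))
  s2 <- simulate_var(var_spec(seed = 7))
  expect_identical(s1$Y, s2$Y)
  expect_false(identical(s1$Y, simulate_var(var_spec(seed = 8))$Y))
  bad <- var_spec(n_series = 2, length = 10,
                  coeffs = array(diag(1.2, 2), c(2, 2, 1)), seed = 1)
  expect_error(simulate_var(bad), "spectral radius")
})

test_that("confounder injection adds shared noise and disjoint shortcuts", {
  sim <- simulate_var(var_spec(n_series = 8, length = 300, seed = 9))
  A <- ((sim$G_true + t(sim$G_true)) > 0) * 1
  diag(A) <- 1
  # identity when disabled
  c0 <- inject_confounders(sim$Y, A, sim$G_true, background_sd = 0,
                           n_shortcuts = 0, seed = 9)
  expect_identical(c0$Y, sim$Y)
  expect_identical(c0$A, A)
  # shortcuts: exact count, disjoint from planted edges, symmetric
  c3 <- inject_confounders(sim$Y, A, sim$G_true, background_sd = 0,
                           n_shortcuts = 3, seed = 9)
  expect_equal(nrow(c3$shortcut_edges), 3)
  expect_equal(sum(c3$A != 0) - sum(A != 0), 6)
  for (r in 1:3) {
    i <- c3$shortcut_edges[r, 1]; j <- c3$shortcut_edges[r, 2]
    expect_equal(sim$G_true[i, j] + sim$G_true[j, i], 0)
    expect_equal(c3$A[i, j], 1)
    expect_equal(c3$A[j, i], 1)
  }
  # shared background noise raises average pairwise correlation
  cb <- inject_confounders(sim$Y, A, sim$G_true, background_sd = 1.5,
                           n_shortcuts = 0, seed = 9)
  mean_cor <- function(Y) mean(cor(t(Y))[upper.tri(diag(nrow(Y)))])
  expect_gt(mean_cor(cb$Y), mean_cor(sim$Y))
  expect_error(inject_confounders(sim$Y, A, sim$G_true, background_sd = -1),
               "nonnegative")
})

test_that("point missingness hits its rate and never unmasks", {
  s <- st_series(matrix(rnorm(100 * 100), 100), diag(100))
  am <- apply_missing(s, missing_spec("point", point_rate = 0.25, seed = 2))
  frac <- 1 - mean(am$series$M)
  se <- sqrt(0.25 * 0.75 / 1e4)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_true(all(am$series$M <= s$M))
  expect_equal(am$eval_mask, (1 - am$series$M) * s$M)
  # rate 0 leaves the mask alone; rate 1 masks everything
  expect_equal(apply_missing(s, missing_spec("point", 0, seed = 1))$series$M, s$M)
  all1 <- apply_missing(s, missing_spec("point", 1, seed = 1))
  expect_equal(sum(all1$series$M), 0)
  expect_equal(all1$eval_mask, s$M)
})

test_that("block missingness produces contiguous runs within the length range", {
  s <- st_series(matrix(rnorm(20 * 200), 20), diag(20))
  ms <- missing_spec("block", block_temporal_rate = 0.02,
                     block_spatial_rate = 0, block_len_range = c(3L, 6L), seed = 3)
  am <- apply_missing(s, ms)
  hid <- 1 - am$series$M
  expect_gt(sum(hid), 0)
  runs <- unlist(apply(hid, 1, function(r) {
    rl <- rle(r); rl$lengths[rl$values == 1]
  }))
  # single blocks are 3..6 steps; window-edge truncation can shorten a few
  # and overlaps can merge longer ones, but typical runs respect the minimum
  expect_gte(median(runs), 3)
})

test_that("training mask sampler hides observed cells only, reproducibly", {
  M <- matrix(1, 10, 10)
  M[1, ] <- 0
  tm <- training_mask_sampler(M, rates = 0.5, seed = 11)
  expect_equal(sum(tm$loss_mask[1, ]), 0)        # missing never a loss target
  n_hidden <- sum(tm$loss_mask)
  se <- sqrt(90 * 0.5 * 0.5)
  expect_lt(abs(n_hidden - 45), 3 * se)
  expect_equal(tm$M_input + tm$loss_mask, M)
  tm2 <- training_mask_sampler(M, rates = 0.5, seed = 11)
  expect_identical(tm$loss_mask, tm2$loss_mask)
  expect_error(training_mask_sampler(M, rates = numeric(0)), "rates")
})

test_that("the planted graph is recoverable from complete data by ridge regression", {
  # sanity oracle for the generator itself: lagged ridge coefficients rank
  # true edges above non-edges
  data <- synthetic_dataset(seed = 3, n_windows = 40)
  Y <- scale(t(data$Y))          # time x series
  TT <- nrow(Y); N <- ncol(Y)
  X <- Y[-TT, ]; Yt <- Y[-1, ]
  B <- solve(crossprod(X) + 0.1 * diag(N), crossprod(X, Yt))  # lag-1 ridge
  W <- abs(B)                    # [source, target]
  off <- !diag(TRUE, N)
  pos <- W[off][data$G_true[off] == 1]
  neg <- W[off][data$G_true[off] == 0]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(auc, 0.9)
})

test_that("the reference dataset wires all pieces together consistently", {
  data <- synthetic_dataset(seed = 1)
  expect_equal(dim(data$series$X), c(15, 480))
  expect_equal(nrow(data$shortcut_edges), 5)
  expect_equal(validate_series(data$series), character(0))
  # adjacency covers every planted edge (both directions) plus self-loops
  expect_true(all(data$series$A[data$G_true == 1 | t(data$G_true) == 1] == 1))
  expect_true(all(diag(data$series$A) == 1))
  # evaluation mask only covers cells with known truth
  expect_true(all(data$series$M + data$eval_mask <= 1))
})
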