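test_that("correlation weights are a proper softmax over the graph context", {
  set.seed(21)
  inst <- rand_sca_instance(N = 3, TT = 4, d = 4)
  # singleton context: isolated node with only a self-loop, T = 1
  A1 <- matrix(1, 1, 1)
  H1 <- array(rnorm(4), c(1, 1, 4))
  cw1 <- correlation_weights(H1, A1, st$sca_params(4), n_heads = 1)
  expect_equal(cw1$alpha1, 1)
  # zero query weights make every score equal -> uniform over |N(i)| * T
  p0 <- inst$params; p0$Wq <- matrix(0, 4, 4)
  cw <- correlation_weights(inst$H, inst$A, p0, n_heads = 1)
  for (i in 1:3) {
    sub <- cw[cw$query_node == i & cw$query_t == 1, ]
    expect_equal(sub$alpha1, rep(1 / nrow(sub), nrow(sub)))
  }
  # normalisation to machine precision for every query
  cw2 <- correlation_weights(inst$H, inst$A, inst$params, n_heads = 2)
  for (h in 1:2) {
    sums <- as.vector(tapply(cw2[[paste0("alpha", h)]],
                             paste(cw2$query_node, cw2$query_t), sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  }
})

test_that("correlation weights match brute-force enumeration", {
  set.seed(22)
  for (rep in 1:5) {
    inst <- rand_sca_instance(N = 3, TT = 3, d = 4)
    nh <- sample(c(1, 2), 1)
    cw <- correlation_weights(inst$H, inst$A, inst$params, n_heads = nh)
    or <- oracle_alpha(inst$H, inst$A, inst$params$Wq, inst$params$Wk, nh)
    for (h in seq_len(nh)) {
      key <- paste(cw$query_node, cw$query_t, cw$key_node, cw$key_t)
      sub <- or[or$head == h, ]
      okey <- paste(sub$query_node, sub$query_t, sub$key_node, sub$key_t)
      expect_equal(cw[[paste0("alpha", h)]],
                   sub$alpha[match(key, okey)], tolerance = 1e-10)
    }
  }
})

test_that("gate probabilities follow the sigmoid scorer exactly", {
  set.seed(23)
  inst <- rand_sca_instance(N = 3, TT = 2, d = 4)
  # all gate weights zero (and zero bias) -> rho = 0.5 everywhere
  p0 <- inst$params
  p0$wc1 <- numeric(4); p0$wc2 <- numeric(4); p0$bc <- 0
  cp0 <- causal_probability(inst$H, inst$A, p0)
  expect_equal(cp0$rho, rep(0.5, nrow(cp0)))
  # scaling the combining weights drives rho to the sign-dependent limits
  pbig <- inst$params
  pbig$wc1 <- pbig$wc1 * 2000; pbig$wc2 <- pbig$wc2 * 2000; pbig$bc <- 0
  cpb <- causal_probability(inst$H, inst$A, pbig)
  expect_gt(mean(cpb$rho < 1e-3 | cpb$rho > 1 - 1e-3), 0.95)
  # random instance matches the direct formula per pair
  cp <- causal_probability(inst$H, inst$A, inst$params)
  for (r in sample(nrow(cp), 10)) {
    expect_equal(cp$rho[r],
                 oracle_rho(inst$H[cp$query_node[r], cp$query_t[r], ],
                            inst$H[cp$key_node[r], cp$key_t[r], ],
                            inst$params),
                 tolerance = 1e-10)
  }
})

test_that("the Gumbel gate is symmetric, temperature-sharp, and unbiased", {
  expect_equal(gumbel_gate(0.5, 1, 0.3, 0.3), 0.5)
  expect_equal(gumbel_gate(0.5, 0.1, 0.7, 0.7), 0.5)
  # tau -> 0 hardens toward the sign of the perturbed logit
  expect_gt(gumbel_gate(0.9, 0.01, 0.5, 0.5), 0.999)
  expect_lt(gumbel_gate(0.1, 0.01, 0.5, 0.5), 0.001)
  # Gumbel-max property: P(beta > 0.5) = rho for any tau
  set.seed(24)
  n <- 1e5
  for (rho in c(0.2, 0.7)) {
    b <- gumbel_gate(rep(rho, n), 0.1, runif(n), runif(n))
    se <- sqrt(rho * (1 - rho) / n)
    expect_lt(abs(mean(b > 0.5) - rho), 4 * se)
  }
  expect_error(gumbel_gate(0.5, 0, 0.5, 0.5), "tau")
})

test_that("messages depend on both endpoints and match direct evaluation", {
  set.seed(25)
  p <- st$sca_params(6)
  hq <- rnorm(6); hk <- rnorm(6)
  v <- message_value(hq, hk, p$msg)
  # direct two-layer evaluation
  pre <- p$msg$W1q %*% hq + p$msg$W1k %*% hk + p$msg$b1
  vref <- as.vector(p$msg$W2 %*% pmax(pre, 0) + p$msg$b2)
  expect_equal(v, vref, tolerance = 1e-12)
  # zero weights give the zero message
  p0 <- p
  p0$msg <- lapply(p0$msg, function(w) w * 0)
  expect_equal(message_value(hq, hk, p0$msg), rep(0, 6))
  # query-dependence
  expect_false(isTRUE(all.equal(v, message_value(rnorm(6), hk, p$msg))))
})

test_that("gated attention output matches brute-force enumeration", {
  set.seed(26)
  for (rep in 1:6) {
    inst <- rand_sca_instance(N = sample(2:4, 1), TT = sample(2:4, 1), d = 4)
    nh <- sample(c(1, 2), 1)
    out <- sca_forward(inst$H, inst$A, inst$params, mode = "eval", n_heads = nh)
    gs <- out$gate_state
    beta_fn <- function(i, t, j, tp) {
      gs$beta[gs$query_node == i & gs$query_t == t &
                gs$key_node == j & gs$key_t == tp][1]
    }
    for (k in 1:3) {
      i <- sample(dim(inst$H)[1], 1); t <- sample(dim(inst$H)[2], 1)
      ref <- oracle_sca_cell(inst$H, inst$A, inst$params, i, t, nh, beta_fn)
      expect_equal(out$H_out[i, t, ], ref, tolerance = 1e-8)
    }
  }
})

test_that("forcing gates open reduces SCA to plain attention with Z = 1", {
  set.seed(27)
  inst <- rand_sca_instance(N = 4, TT = 3, d = 4)
  out <- sca_forward(inst$H, inst$A, inst$params, mode = "eval", n_heads = 2,
                     no_gate = TRUE)
  expect_true(all(abs(out$Z - 1) < 1e-9))
  ref <- oracle_sca_cell(inst$H, inst$A, inst$params, 2, 2, 2,
                         function(...) 1)
  expect_equal(out$H_out[2, 2, ], ref, tolerance = 1e-8)
})

test_that("all-closed queries are floored to zero and flagged", {
  set.seed(28)
  inst <- rand_sca_instance(N = 3, TT = 2, d = 4)
  p <- inst$params
  p$bc <- -50   # sigmoid ~ 0: every hard gate closes
  out <- sca_forward(inst$H, inst$A, p, mode = "eval", n_heads = 1)
  expect_true(all(out$H_out == 0))
  expect_equal(length(attr(out$gate_state, "flagged")), prod(dim(inst$H)[1:2]))
})

test_that("non-adjacent nodes can never influence a query (locality)", {
  set.seed(29)
  A <- matrix(0, 3, 3); diag(A) <- 1; A[1, 2] <- 1   # node 3 isolated from 1
  H <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  p <- st$sca_params(4)
  out1 <- sca_forward(H, A, p, mode = "eval", n_heads = 2)
  H2 <- H; H2[3, , ] <- H2[3, , ] + 5
  out2 <- sca_forward(H2, A, p, mode = "eval", n_heads = 2)
  expect_equal(out1$H_out[1, , ], out2$H_out[1, , ], tolerance = 1e-12)
  expect_equal(out1$H_out[2, , ], out2$H_out[2, , ], tolerance = 1e-12)
})

test_that("relabeling nodes permutes the output consistently", {
  set.seed(30)
  inst <- rand_sca_instance(N = 4, TT = 3, d = 4)
  perm <- c(3, 1, 4, 2)
  out <- sca_forward(inst$H, inst$A, inst$params, mode = "eval", n_heads = 2)
  Hp <- inst$H[perm, , , drop = FALSE]
  Ap <- inst$A[perm, perm]
  outp <- sca_forward(Hp, Ap, inst$params, mode = "eval", n_heads = 2)
  expect_equal(outp$H_out, out$H_out[perm, , , drop = FALSE], tolerance = 1e-10)
})

test_that("constrained mode restricts keys to the past", {
  set.seed(31)
  inst <- rand_sca_instance(N = 3, TT = 4, d = 4)
  out <- sca_forward(inst$H, inst$A, inst$params, mode = "eval", n_heads = 1,
                     constrained = TRUE)
  expect_true(all(out$gate_state$key_t <= out$gate_state$query_t))
  # perturbing a strictly-future key leaves the query output unchanged
  H2 <- inst$H; H2[, 4, ] <- H2[, 4, ] + 3
  out2 <- sca_forward(H2, inst$A, inst$params, mode = "eval", n_heads = 1,
                      constrained = TRUE)
  expect_equal(out$H_out[, 1:3, ], out2$H_out[, 1:3, ], tolerance = 1e-10)
})

test_that("gate state exports round-trip through TSV", {
  set.seed(32)
  inst <- rand_sca_instance(N = 2, TT = 2, d = 4)
  out <- sca_forward(inst$H, inst$A, inst$params, mode = "eval")
  tmp <- tempfile(fileext = ".tsv")
  write_gate_state(out$gate_state, tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(out$gate_state))
  expect_equal(back$rho, out$gate_state$rho, tolerance = 1e-6)
})
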