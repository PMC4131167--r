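test_that("pair_update handles the closed-form special cases", {
  # zero gradient at the origin: zero is optimal under any penalties
  expect_equal(pair_update(0, 0, 1, 2, 0.3, 0.7), c(0, 0))
  # lambda2 = 0 decouples into two scalar soft-thresholds S(c, w) / a
  expect_equal(pair_update(2, -1, 1, 1, 0.5, 0), c(1.5, -0.5))
  # strong fusion pulls both coordinates to the fused solution
  fused <- pair_update(1, 0.8, 1, 1, 0.2, 0.5)
  expect_equal(fused[1], fused[2])
  oracle <- grid_oracle_pair(1, 0.8, 1, 1, 0.2, 0.5)
  expect_equal(fused, c(0.7, 0.7), tolerance = 2e-3)
  expect_lt(max(abs(fused - c(oracle$b1, oracle$b2))), 2e-3)
  expect_error(pair_update(1, 1, 0, 1, 0.1, 0.1), "positive")
})

test_that("pair_update matches the dense grid-search oracle on random draws", {
  withr::local_seed(42)
  for (k in 1:200) {
    a1 <- runif(1, 0.8, 3)
    a2 <- runif(1, 0.8, 3)
    c1 <- runif(1, -1.8, 1.8)
    c2 <- runif(1, -1.8, 1.8)
    w <- runif(1, 0, 1)
    l2 <- runif(1, 0, 1)
    b <- pair_update(c1, c2, a1, a2, w, l2)
    o <- grid_oracle_pair(c1, c2, a1, a2, w, l2)
    expect_lt(max(abs(b - c(o$b1, o$b2))), 2e-3)
    # and the exact solution can only be at least as good as the grid's
    expect_lte(g_pair(b[1], b[2], c1, c2, a1, a2, w, l2), o$g + 1e-12)
  }
})

test_that("objective_value matches an independent term-by-term recomputation", {
  withr::local_seed(7)
  fx <- make_pair_data(p = 5, n = 10, seed = 3)
  d <- fx$data
  params <- kddn_params(lambda1 = 0.4, lambda2 = 0.15, theta = 0.5)
  wcol <- c(0, 1, 1, 0, 0)
  beta <- cbind(c(0.3, 0, -0.2, 0.1, 0), c(-0.1, 0, 0.25, 0, 0))
  beta[2, ] <- 0  # target node constraint
  node <- fit_node(2, d, params = kddn_params(lambda1 = 1, lambda2 = 0))
  got <- objective_value(node, wcol, params, beta = beta)

  # independent plain-loop re-summation on the problem's own matrices
  rss <- 0
  for (s in seq_along(node$y)) {
    n1 <- nrow(node$X1)
    pred <- if (s <= n1) sum(node$X1[s, ] * beta[, 1]) else
      sum(node$X2[s - n1, ] * beta[, 2])
    rss <- rss + (node$y[s] - pred)^2
  }
  pen1 <- 0
  pen2 <- 0
  for (j in 1:5) {
    pen1 <- pen1 + (1 - wcol[j] * params$theta) *
      (abs(beta[j, 1]) + abs(beta[j, 2]))
    pen2 <- pen2 + abs(beta[j, 1] - beta[j, 2])
  }
  want <- 0.5 * rss + params$lambda1 * pen1 + params$lambda2 * pen2
  expect_equal(got, want, tolerance = 1e-10)

  # beta = 0: penalties vanish, objective is half the squared response norm
  expect_equal(objective_value(node, wcol, params, beta = matrix(0, 5, 2)),
               0.5 * sum(node$y^2))
  # theta = 1 with full knowledge kills the lasso term entirely
  p_full <- kddn_params(lambda1 = 5, lambda2 = 0, theta = 1)
  expect_equal(objective_value(node, rep(1, 5), p_full, beta = beta),
               0.5 * rss)
  expect_error(objective_value(node, wcol[1:3], params), "length")
})

test_that("fit_node kills every coordinate when lambda1 dominates", {
  fx <- make_pair_data(p = 8, n = 30, seed = 5)
  sm <- kddn:::scaled_matrices(fx$data)
  cmax <- max(abs(crossprod(sm$X1)), abs(crossprod(sm$X2)))
  node <- fit_node(3, fx$data,
                   params = kddn_params(lambda1 = cmax * 1.01, lambda2 = 0))
  expect_true(all(node$beta == 0))
  expect_equal(node$iters, 1L)
})

test_that("a p = 2 problem reduces to a single pair update", {
  fx <- make_pair_data(p = 12, n = 25, seed = 11)
  d <- fx$data
  two <- kddn_data(d$X1[, 1:2], d$X2[, 1:2], genes = d$genes[1:2])
  two <- standardize(two)
  params <- kddn_params(lambda1 = 0.2, lambda2 = 0.07)
  node <- fit_node(1, two, params = params)
  sm <- kddn:::scaled_matrices(two)
  b <- pair_update(sum(sm$X1[, 2] * sm$X1[, 1]),
                   sum(sm$X2[, 2] * sm$X2[, 1]),
                   sum(sm$X1[, 2]^2), sum(sm$X2[, 2]^2),
                   params$lambda1, params$lambda2)
  expect_equal(unname(node$beta[2, ]), b, tolerance = 1e-8)
  expect_equal(unname(node$beta[1, ]), c(0, 0))
})

test_that("the objective is non-increasing across sweeps", {
  for (s in 1:5) {
    fx <- make_pair_data(p = 10, n = 30, seed = 20 + s)
    node <- fit_node(1, fx$data,
                     params = kddn_params(lambda1 = 0.15, lambda2 = 0.05),
                     trace = TRUE)
    tr <- node$objective_trace
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("non-convergence reports the node and last change", {
  fx <- make_pair_data(p = 10, n = 30, seed = 31)
  expect_error(
    fit_node(4, fx$data, params = kddn_params(lambda1 = 0.1, lambda2 = 0.01),
             max_iter = 1L),
    "node 4.*did not converge")
})

test_that("fit_node agrees with a generic convex-optimization oracle", {
  withr::local_seed(99)
  for (s in 1:4) {
    fx <- make_pair_data(p = 6, n = 30, seed = 40 + s)
    params <- kddn_params(lambda1 = runif(1, 0.1, 0.5),
                          lambda2 = runif(1, 0, 0.2),
                          theta = sample(c(0, 0.5), 1))
    know <- sample_random_knowledge(6, 4, seed = s, genes = fx$data$genes)
    i <- sample(6, 1)
    node <- fit_node(i, fx$data, knowledge = know, params = params,
                     tol = 1e-9)
    f_ours <- objective_value(node, know$W[, i], params)
    sm <- kddn:::scaled_matrices(fx$data)
    w <- params$lambda1 * (1 - know$W[, i] * params$theta)
    f_oracle <- node_oracle_python(sm$X1, sm$X2, i, w, params$lambda2)
    expect_lt(abs(f_ours - f_oracle), 1e-6)
  }
})
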