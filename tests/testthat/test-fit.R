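fx_fit <- make_pair_data(p = 15, n = 60, seed = 101)

test_that("theta = 0 output is invariant to the prior's content", {
  params <- kddn_params(lambda1 = 0.35, lambda2 = 0.02, theta = 0)
  k1 <- sample_random_knowledge(15, 20, seed = 1, genes = fx_fit$data$genes)
  k2 <- sample_random_knowledge(15, 40, seed = 2, genes = fx_fit$data$genes)
  f1 <- kddn_fit(fx_fit$data, knowledge = k1, params = params)
  f2 <- kddn_fit(fx_fit$data, knowledge = k2, params = params)
  expect_identical(f1$beta1, f2$beta1)
  expect_identical(f1$beta2, f2$beta2)
  expect_identical(f1$edges, f2$edges)
})

test_that("large fusion penalty forces identical edge sets", {
  sm <- kddn:::scaled_matrices(fx_fit$data)
  big <- 0.3 + max(abs(crossprod(sm$X1)), abs(crossprod(sm$X2)))
  fit <- kddn_fit(fx_fit$data,
                  params = kddn_params(lambda1 = 0.3, lambda2 = big))
  expect_equal(sum(fit$edges$condition != "both"), 0)
  expect_equal(fit$beta1, fit$beta2)
})

test_that("lambda2 = 0, theta = 0 reproduces two independent lasso fits", {
  skip_if_not_installed("glmnet")
  d <- fx_fit$data
  p <- length(d$genes)
  lambda1 <- 0.3
  fit <- kddn_fit(d, params = kddn_params(lambda1 = lambda1, lambda2 = 0),
                  tol = 1e-8)
  # our joint problem at lambda2 = 0 decouples; each condition's node
  # regression is a lasso whose glmnet-scale penalty is lambda1 / 2
  for (cond in 1:2) {
    X <- if (cond == 1) d$X1 else d$X2
    B <- if (cond == 1) fit$beta1 else fit$beta2
    for (i in c(1, 5, 9)) {
      g <- glmnet::glmnet(X[, -i], X[, i], lambda = lambda1 / 2,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
      bg <- numeric(p)
      bg[-i] <- as.numeric(g$beta)
      expect_equal(unname(B[, i]), bg, tolerance = 1e-6)
    }
  }
})

test_that("swapping condition labels swaps the edge sets exactly", {
  d <- fx_fit$data
  swapped <- kddn_data(d$X2, d$X1, genes = d$genes)
  params <- kddn_params(lambda1 = 0.3, lambda2 = 0.05)
  f1 <- kddn_fit(d, params = params)
  f2 <- kddn_fit(swapped, params = params)
  expect_equal(f1$beta1, f2$beta2, tolerance = 1e-12)
  expect_equal(f1$beta2, f2$beta1, tolerance = 1e-12)
  expect_identical(f1$beta1 != 0, f2$beta2 != 0)
  expect_identical(f1$beta2 != 0, f2$beta1 != 0)
  remap <- c(both = "both", cond1 = "cond2", cond2 = "cond1")
  e1 <- f1$edges
  e1$condition <- unname(remap[e1$condition])
  expect_equal(dplyr::arrange(e1, node_a, node_b)$condition,
               dplyr::arrange(f2$edges, node_a, node_b)$condition)
})

test_that("the solution is invariant to gene ordering up to relabeling", {
  d <- fx_fit$data
  perm <- withr::with_seed(8, sample(length(d$genes)))
  dp <- kddn_data(d$X1[, perm], d$X2[, perm], genes = d$genes[perm])
  params <- kddn_params(lambda1 = 0.3, lambda2 = 0.05)
  f1 <- kddn_fit(d, params = params, tol = 1e-8)
  f2 <- kddn_fit(dp, params = params, tol = 1e-8)
  key <- function(f) {
    et <- as_edge_table(f)
    sort(paste(pmin(et$node_a, et$node_b), pmax(et$node_a, et$node_b),
               et$condition))
  }
  expect_equal(key(f1), key(f2))
  expect_equal(f1$beta1[d$genes[perm], d$genes[perm]], f2$beta1,
               tolerance = 1e-5)
})

test_that("knowledge at theta = 1 removes the penalty on supported pairs", {
  # orthogonal design: the fitted coefficient on an unpenalized pair is
  # the plain projection c / a
  n <- 24
  q <- withr::with_seed(3, qr.Q(qr(matrix(rnorm(n * 4), n, 4))))
  x <- q %*% diag(4) # orthonormal columns
  y1 <- 0.8 * x[, 2] + 0.1 * x[, 3]
  y2 <- 0.5 * x[, 2]
  d <- standardize(kddn_data(cbind(y1, x[, 2:4]), cbind(y2, x[, 2:4]),
                             genes = c("y", "a", "b", "c")))
  W <- matrix(0, 4, 4, dimnames = list(d$genes, d$genes))
  W["a", "y"] <- W["y", "a"] <- 1
  know <- kddn_prior(W)
  sm <- kddn:::scaled_matrices(d)
  lam <- 0.95 * max(abs(crossprod(sm$X1)[-1, 1]),
                    abs(crossprod(sm$X2)[-1, 1]))
  node <- fit_node("y", d, knowledge = know,
                   params = kddn_params(lambda1 = lam, lambda2 = 0,
                                        theta = 1), tol = 1e-10)
  proj1 <- sum(sm$X1[, 2] * sm$X1[, 1]) / sum(sm$X1[, 2]^2)
  expect_equal(unname(node$beta["a", "cond1"]), proj1, tolerance = 1e-6)
  expect_true(node$beta["a", "cond1"] != 0)
})

test_that("the AND symmetrization is at least as strict as OR", {
  params <- kddn_params(lambda1 = 0.28, lambda2 = 0.02)
  f_or <- kddn_fit(fx_fit$data, params = params, symmetrize = "or")
  f_and <- kddn_fit(fx_fit$data, params = params, symmetrize = "and")
  key <- function(f, cond) {
    et <- as_edge_table(f)
    et <- et[et$condition %in% c(cond, "both"), ]
    paste(et$node_a, et$node_b)
  }
  for (cond in c("cond1", "cond2")) {
    expect_true(all(key(f_and, cond) %in% key(f_or, cond)))
  }
})

test_that("edge tables carry both coefficient scales coherently", {
  fx <- make_pair_data(p = 12, n = 50, seed = 202)
  raw <- withr::with_seed(1, {
    x1 <- fx$data$X1 %*% diag(runif(12, 0.5, 3))
    x2 <- fx$data$X2 %*% diag(runif(12, 0.5, 3))
    kddn_data(x1, x2, genes = fx$data$genes)
  })
  fit <- kddn_fit(raw, params = kddn_params(lambda1 = 0.3, lambda2 = 0.02))
  std <- tidy(fit, scale = "standardized")
  ori <- tidy(fit, scale = "original")
  expect_equal(nrow(std), nrow(ori))
  if (nrow(std) > 0) {
    s <- fit$scales$cond1
    expect_equal(ori$beta1_ab,
                 std$beta1_ab * s[std$node_b] / s[std$node_a],
                 ignore_attr = TRUE)
  }
})
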