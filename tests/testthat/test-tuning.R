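test_that("select_lambda1 reproduces the false-join closed form", {
  fx <- make_pair_data(p = 12, n = 40, seed = 1)
  # independent evaluation of the normal quantile form at these sizes
  expect_equal(select_lambda1(fx$data, 0.05),
               2 / sqrt(40) * qnorm(1 - 0.05 / (2 * 144)), tolerance = 1e-12)
  # reference value computed with the system python (scipy.stats.norm.ppf)
  # for p = 100, N = 150, alpha1 = 0.05: (2/sqrt(150)) * ppf(1 - 0.05/20000)
  big <- make_pair_data(p = 100, n = 150, seed = 2)
  expect_equal(select_lambda1(big$data, 0.05), 0.7454267149, tolerance = 1e-8)

  # monotone: decreasing in alpha1, increasing in p
  l_alpha <- vapply(c(0.01, 0.05, 0.2, 0.999), select_lambda1,
                    numeric(1), data = fx$data)
  expect_true(all(diff(l_alpha) < 0))
  expect_true(all(is.finite(l_alpha)))
  expect_lt(select_lambda1(fx$data, 0.05),
            select_lambda1(make_pair_data(p = 24, n = 40, seed = 1)$data, 0.05))
  expect_error(select_lambda1(fx$data, 0), "alpha1")
  expect_error(select_lambda1(fx$data, 1), "alpha1")
})

test_that("unequal sample sizes use the smaller condition", {
  fx <- make_pair_data(p = 10, n = 60, seed = 3)
  d <- fx$data
  uneq <- standardize(kddn_data(d$X1, d$X2[1:30, ], genes = d$genes))
  expect_equal(select_lambda1(uneq, 0.05),
               2 / sqrt(30) * qnorm(1 - 0.05 / (2 * 100)))
})

test_that("random knowledge draws are uniform, symmetric and seeded", {
  expect_equal(sample_random_knowledge(10, 0, seed = 1)$M, 0L)
  expect_true(all(sample_random_knowledge(10, 0, seed = 1)$W == 0))
  full <- sample_random_knowledge(10, 45, seed = 1)
  expect_equal(full$M, 45L)
  expect_true(all(full$W[upper.tri(full$W)] == 1))
  expect_error(sample_random_knowledge(10, 46), "between 0 and")

  w1 <- sample_random_knowledge(40, 100, seed = 7)
  w2 <- sample_random_knowledge(40, 100, seed = 7)
  expect_identical(w1$W, w2$W)
  expect_identical(w1$W, t(w1$W))
  expect_true(all(diag(w1$W) == 0))

  # inclusion frequency of each pair matches the hypergeometric marginal
  p <- 100
  M <- 200
  draws <- 2000
  counts <- matrix(0, p, p)
  for (s in seq_len(draws)) {
    counts <- counts + sample_random_knowledge(p, M, seed = s)$W
  }
  freq <- counts[upper.tri(counts)] / draws
  expected <- M / (p * (p - 1) / 2)
  se <- sqrt(expected * (1 - expected) / draws)
  expect_lt(max(abs(freq - expected)), 4.5 * se) # max over 4950 pairs
  expect_lt(abs(mean(freq) - expected), 1e-12)
})

fx_tune <- make_pair_data(p = 20, n = 80, seed = 55)

test_that("select_lambda2 returns a calibrated, deterministic value", {
  d <- fx_tune$data
  lambda1 <- select_lambda1(d, 0.05)
  expect_error(select_lambda2(d, lambda1 = lambda1, B = 10), "at least 20")

  l2a <- select_lambda2(d, lambda1 = lambda1, B = 25, n_grid = 8, seed = 9)
  l2b <- select_lambda2(d, lambda1 = lambda1, B = 25, n_grid = 8, seed = 9)
  expect_identical(as.numeric(l2a), as.numeric(l2b))
  expect_identical(attr(l2a, "null_rate"), attr(l2b, "null_rate"))

  # a single huge candidate is selected and admits no null differentials
  big <- lambda1 * 50
  l2c <- select_lambda2(d, lambda1 = lambda1, B = 25, grid = big, seed = 9)
  expect_equal(as.numeric(l2c), big)
  expect_equal(unname(attr(l2c, "null_rate")), 0)
})

test_that("identical conditions admit no differential edges at the selected level", {
  d0 <- fx_tune$data
  same <- standardize(kddn_data(d0$X1, d0$X1, genes = d0$genes))
  lambda1 <- select_lambda1(same, 0.05)
  l2 <- select_lambda2(same, lambda1 = lambda1, B = 25, n_grid = 8, seed = 4)
  fit <- kddn_fit(same, params = kddn_params(lambda1 = lambda1,
                                             lambda2 = as.numeric(l2)))
  expect_equal(sum(fit$edges$condition != "both"), 0)
})

test_that("select_theta obeys its own degradation constraint", {
  fx <- make_pair_data(p = 20, n = 100, seed = 77)
  d <- fx$data
  lambda1 <- select_lambda1(d, 0.05)
  params <- kddn_params(lambda1 = lambda1, lambda2 = lambda1 / 50,
                        delta = 0.1)
  cal <- select_theta(d, M = nrow(fx$truth$E_common), params = params,
                      grid = seq(0, 1, 0.1), R = 30, seed = 12)
  tab <- cal$table
  expect_equal(tab$mean_distance[tab$theta == 0], 0)
  expect_true(cal$theta_hat %in% tab$theta)
  expect_lte(tab$mean_distance[tab$theta == cal$theta_hat], 0.1)
  # direct recomputation: mean at theta_hat from the stored draws
  expect_equal(mean(cal$distances[, as.character(cal$theta_hat)]),
               unname(tab$mean_distance[tab$theta == cal$theta_hat]))
  # no grid point's mean exceeds the next one's by more than 2 MC SEs
  se <- tab$sd_distance / sqrt(cal$R)
  slack <- 2 * (se[-1] + se[-length(se)])
  expect_true(all(diff(tab$mean_distance) >= -slack))
  # determinism
  cal2 <- select_theta(d, M = nrow(fx$truth$E_common), params = params,
                       grid = seq(0, 1, 0.1), R = 30, seed = 12)
  expect_identical(cal$theta_hat, cal2$theta_hat)
  expect_identical(cal$distances, cal2$distances)
})

test_that("select_theta boundary behavior", {
  fx <- make_pair_data(p = 15, n = 80, seed = 31)
  d <- fx$data
  lambda1 <- select_lambda1(d, 0.2)
  params <- kddn_params(lambda1 = lambda1, lambda2 = 0.01, delta = 0.99)
  # no knowledge edges: every theta leaves the network untouched
  cal0 <- select_theta(d, M = 0, params = params, grid = c(0, 0.5, 1),
                       R = 5, seed = 5)
  expect_equal(cal0$theta_hat, 1)
  expect_true(all(cal0$distances == 0))
  # a slack budget never binds: the largest grid value is returned
  cal <- select_theta(d, M = 1, params = params, grid = c(0, 0.5, 1),
                      R = 10, seed = 5)
  expect_equal(cal$theta_hat, 1)
  # an empty data-driven network cannot be calibrated
  noise <- withr::with_seed(2, standardize(kddn_data(
    matrix(rnorm(45 * 15), 45, 15), matrix(rnorm(45 * 15), 45, 15))))
  expect_error(
    select_theta(noise, M = 3,
                 params = kddn_params(lambda1 = 50, lambda2 = 0.01)),
    "empty data-driven network")
})
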