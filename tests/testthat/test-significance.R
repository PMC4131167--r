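test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  expect_equal(adjust_fdr(0.01), 0.01)
  # step-up by hand: min over k >= i of p_(k) * m / k, here all collapse
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  # order preserved under shuffling
  p <- c(0.2, 0.001, 0.9, 0.04)
  expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
  expect_error(adjust_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("identical conditions give a degenerate statistic and p = 1", {
  fx <- make_pair_data(p = 8, n = 30, seed = 61)
  d0 <- fx$data
  same <- standardize(kddn_data(d0$X1, d0$X1, genes = d0$genes))
  params <- kddn_params(lambda1 = 0.4, lambda2 = 0.05)
  res <- differential_edge_pvalue(same, c(1, 2), params, B = 19, seed = 1,
                                  check_differential = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$pvalue, 1)
})

test_that("the add-one permutation formula gives p = 1/(B+1) for a dominant effect", {
  # plant a dependence present only in condition 1, far above noise
  n <- 60
  d <- withr::with_seed(5, {
    z <- rnorm(n)
    x1 <- cbind(a = z, b = 0.95 * z + 0.1 * rnorm(n), c = rnorm(n),
                d = rnorm(n))
    x2 <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, colnames(x1)))
    standardize(kddn_data(x1, x2))
  })
  params <- kddn_params(lambda1 = select_lambda1(d), lambda2 = 0.01)
  res <- differential_edge_pvalue(d, c("a", "b"), params, B = 19, seed = 2)
  expect_equal(res$pvalue, 1 / 20)
  expect_error(differential_edge_pvalue(d, c("a", "b"), params, B = 10),
               "at least 19")
  expect_error(differential_edge_pvalue(d, c("c", "d"), params, B = 19,
                                        seed = 3),
               "not differential")
})

test_that("p-values are invariant to condition relabeling", {
  fx <- make_pair_data(p = 8, n = 40, seed = 71)
  d <- fx$data
  swapped <- kddn_data(d$X2, d$X1, genes = d$genes)
  params <- kddn_params(lambda1 = 0.35, lambda2 = 0.02)
  r1 <- differential_edge_pvalue(d, c(1, 2), params, B = 49, seed = 11,
                                 check_differential = FALSE)
  r2 <- differential_edge_pvalue(swapped, c(1, 2), params, B = 49, seed = 11,
                                 check_differential = FALSE)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  # the permutation null resamples the same pooled rows, so the p-values
  # agree up to Monte-Carlo resolution
  expect_lt(abs(r1$pvalue - r2$pvalue), 0.15)
})

test_that("a strongly rewired edge is detected with high power", {
  # one planted edge present only in condition 1; power grows with the
  # planted partial correlation once it clears the false-join selection
  # threshold (about 0.35 in correlation units at p = 15, n = 100)
  power_at <- function(partial, n_rep, B = 99) {
    hits <- 0
    for (s in seq_len(n_rep)) {
      d <- withr::with_seed(100 + s, {
        p <- 15
        om1 <- diag(p)
        om1[1, 2] <- om1[2, 1] <- -partial
        x1 <- MASS::mvrnorm(100, rep(0, p), solve(om1))
        x2 <- MASS::mvrnorm(100, rep(0, p), diag(p))
        standardize(kddn_data(x1, x2))
      })
      params <- kddn_params(lambda1 = select_lambda1(d), lambda2 = 0.05)
      res <- differential_edge_pvalue(d, c(1, 2), params, B = B,
                                      seed = 200 + s,
                                      check_differential = FALSE)
      hits <- hits + (res$pvalue <= 0.05)
    }
    hits / n_rep
  }
  # well above threshold: essentially always significant
  expect_gte(power_at(0.6, 12), 0.9)
  # at the threshold the test still has real, if partial, power
  expect_gte(power_at(0.4, 12), 0.25)
})

test_that("edge_significance fills p and q for differential edges only", {
  fx <- make_pair_data(p = 12, n = 60, seed = 81)
  fit <- kddn_fit(fx$data, params = kddn_params(lambda1 = 0.3,
                                                lambda2 = 0.005))
  fit <- edge_significance(fit, B = 29, seed = 5)
  e <- fit$edges
  dif <- e$condition != "both"
  if (any(dif)) {
    expect_true(all(!is.na(e$pvalue[dif])))
    expect_true(all(e$pvalue[dif] >= 1 / 30 & e$pvalue[dif] <= 1))
    expect_equal(e$qvalue[dif], adjust_fdr(e$pvalue[dif]))
  }
  expect_true(all(is.na(e$pvalue[!dif])))
  # deterministic given the seed
  fit2 <- edge_significance(
    kddn_fit(fx$data, params = kddn_params(lambda1 = 0.3, lambda2 = 0.005)),
    B = 29, seed = 5)
  expect_identical(fit$edges, fit2$edges)
})

test_that("permutation p-values are super-uniform under the null", {
  # fixed edge, both conditions identically distributed: by
  # exchangeability the rejection rate at 0.05 stays at or below
  # 0.05 plus Monte-Carlo slack
  n_rep <- 80
  hits <- 0
  for (s in seq_len(n_rep)) {
    d <- withr::with_seed(s, {
      sig <- 0.35^abs(outer(1:10, 1:10, "-"))
      standardize(kddn_data(MASS::mvrnorm(40, rep(0, 10), sig),
                            MASS::mvrnorm(40, rep(0, 10), sig)))
    })
    params <- kddn_params(lambda1 = 0.35, lambda2 = 0.02)
    r <- differential_edge_pvalue(d, c(1, 2), params, B = 39,
                                  seed = 100 + s,
                                  check_differential = FALSE)
    hits <- hits + (r$pvalue <= 0.05)
  }
  expect_lte(hits / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})
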