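#' Worst-case random-knowledge robustness study
#'
#' End-to-end simulation assessment of the degradation bound behind the
#' knowledge-weight calibration. One GMRF ground-truth pair is generated
#' and sampled, the penalties are selected from the data (sparsity by
#' false-join control, fusion by permutation calibration at `theta = 0`,
#' knowledge weight by [select_theta()] with `M` set to the number of
#' common true edges), and then `fresh_draws` new completely random priors
#' are incorporated at the selected weight. Two quantities summarize the
#' outcome:
#' \describe{
#'   \item{`mean_relative_distance`}{mean of
#'     \eqn{d(G_X, G_{X,W_R,\hat\theta}) / |E_X|} over the fresh draws —
#'     the quantity the calibration promises to keep at or below `delta`.}
#'   \item{`error_rate_increase_pp`}{the increase, in percentage points,
#'     of the ground-truth error rate \eqn{d(G_T, \cdot) / |E_T|} of the
#'     random-knowledge fits over the purely data-driven fit; the
#'     degradation bound states this stays within `delta` as well.}
#' }
#'
#' @param p Nodes in the simulated network.
#' @param n Samples per condition.
#' @param delta Degradation budget.
#' @param rewire_fraction Edge fraction rewired between conditions.
#' @param theta_grid Grid for the knowledge-weight calibration.
#' @param R Random-knowledge draws per grid value during calibration.
#' @param fresh_draws Fresh random priors for the held-out assessment.
#' @param lambda2_splits Pseudo-splits in the fusion-penalty calibration.
#' @param alpha1,alpha2 Selection levels.
#' @param seed Integer seed; the whole study is deterministic given it.
#'
#' @return A list with `mean_relative_distance`, `error_rate_increase_pp`,
#'   `data_only_error_rate`, `theta_hat`, `lambda1`, `lambda2`,
#'   `n_edges_gx` (labeled), `n_edges_truth` (labeled), `M`, `p`, `n` and
#'   the per-draw vectors `fresh_distances` and `fresh_error_rates`.
#' @export
knowledge_robustness_study <- function(p = 100, n = 150, delta = 0.1,
                                       rewire_fraction = 0.1,
                                       theta_grid = seq(0, 1, by = 0.1),
                                       R = 100, fresh_draws = 100,
                                       lambda2_splits = 50, alpha1 = 0.05,
                                       alpha2 = 0.05, seed = NULL) {
  seeds <- with_seed_or_not(seed, sample.int(.Machine$integer.max, 5))
  truth <- perturb_network(simulate_gmrf_truth(p, seed = seeds[1]),
                           rewire_fraction, seed = seeds[1])
  data <- standardize(sample_condition_data(truth, n, seed = seeds[2]))
  lambda1 <- select_lambda1(data, alpha1)
  lambda2 <- as.numeric(
    select_lambda2(data, NULL, lambda1 = lambda1, theta = 0,
                   alpha2 = alpha2, B = lambda2_splits, seed = seeds[3]))
  m_common <- nrow(truth$E_common)
  cal <- select_theta(data, M = m_common,
                      params = kddn_params(lambda1 = lambda1,
                                           lambda2 = lambda2, delta = delta),
                      grid = theta_grid, R = R, seed = seeds[4])
  theta_hat <- cal$theta_hat

  sm <- scaled_matrices(data)
  gx <- fit_supports(sm$X1, sm$X2, matrix(0, p, p), lambda1, 0, lambda2)
  n_ex <- support_n_labeled(gx)
  st <- truth_supports(truth)
  n_et <- support_n_labeled(st)
  err0 <- support_distance(st, gx) / n_et

  draw_seeds <- with_seed_or_not(seeds[5],
    sample.int(.Machine$integer.max, fresh_draws))
  fresh <- vapply(draw_seeds, function(s) {
    pr <- sample_random_knowledge(p, m_common, seed = s, genes = data$genes)
    fit <- fit_supports(sm$X1, sm$X2, pr$W, lambda1, theta_hat, lambda2)
    c(dist = support_distance(gx, fit) / n_ex,
      err = support_distance(st, fit) / n_et)
  }, numeric(2))

  list(mean_relative_distance = mean(fresh["dist", ]),
       error_rate_increase_pp = 100 * (mean(fresh["err", ]) - err0),
       data_only_error_rate = err0,
       theta_hat = theta_hat, calibration = cal,
       lambda1 = lambda1, lambda2 = lambda2,
       n_edges_gx = n_ex, n_edges_truth = n_et, M = m_common,
       p = p, n = n,
       fresh_distances = unname(fresh["dist", ]),
       fresh_error_rates = unname(fresh["err", ]))
}

# Ground-truth labeled supports in the same form fit_supports() returns.
truth_supports <- function(truth) {
  p <- truth$p
  mk <- function(e) {
    s <- matrix(FALSE, p, p)
    if (nrow(e)) {
      s[e] <- TRUE
      s[e[, c(2, 1), drop = FALSE]] <- TRUE
    }
    s
  }
  list(S1 = mk(truth$edges1), S2 = mk(truth$edges2))
}
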