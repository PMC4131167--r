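#' Select the sparsity penalty by false-join control
#'
#' Closed-form neighborhood-selection level controlling the probability of
#' falsely joining two distinct connectivity components of the graph:
#' \deqn{\lambda_1 = \frac{2\hat\sigma}{\sqrt{N_c}}
#'   \Phi^{-1}\!\left(1 - \frac{\alpha_1}{2 p^2}\right),}
#' with \eqn{\hat\sigma = 1} for standardized responses and \eqn{N_c} the
#' per-condition sample size (the smaller of the two when they differ,
#' which is the conservative choice). The value is decreasing in
#' `alpha1` and increasing in `p`.
#'
#' @param data A [kddn_data].
#' @param alpha1 False-join level in (0, 1).
#' @return The scalar penalty `lambda1`.
#' @examples
#' truth <- perturb_network(simulate_gmrf_truth(20, seed = 1), seed = 2)
#' d <- sample_condition_data(truth, 50, seed = 3)
#' select_lambda1(d, alpha1 = 0.05)
#' @export
select_lambda1 <- function(data, alpha1 = 0.05) {
  stopifnot(inherits(data, "kddn_data"))
  if (!is.numeric(alpha1) || length(alpha1) != 1 || alpha1 <= 0 || alpha1 >= 1) {
    stop("alpha1 must be in (0, 1)", call. = FALSE)
  }
  p <- length(data$genes)
  n_c <- min(n_samples(data))
  2 / sqrt(n_c) * qnorm(1 - alpha1 / (2 * p^2))
}

#' Default fusion-penalty candidate grid
#'
#' Log-spaced candidates in `[lambda1 / 100, lambda1]`; in practice a
#' fusion penalty beyond the sparsity penalty is never active.
#'
#' @param lambda1 The selected sparsity penalty.
#' @param n Number of candidates.
#' @return Ascending numeric vector of length `n`.
#' @export
lambda2_grid <- function(lambda1, n = 20) {
  exp(seq(log(lambda1 / 100), log(lambda1), length.out = n))
}

# Fast internal fit: symmetrized (OR) support matrices only.
fit_supports <- function(X1s, X2s, W, lambda1, theta, lambda2,
                         tol = 1e-6, max_iter = 1000L) {
  res <- fit_network_cpp(X1s, X2s, W, lambda1, theta, lambda2, tol,
                         as.integer(max_iter))
  if (!all(res$converged)) {
    bad <- which(!res$converged)[1]
    stop("node ", bad, " did not converge in ", max_iter, " sweeps",
         call. = FALSE)
  }
  S1 <- res$B1 != 0
  S2 <- res$B2 != 0
  list(S1 = S1 | t(S1), S2 = S2 | t(S2))
}

# Labeled graph edit distance between two support-pair lists: insertions
# plus deletions per condition.
support_distance <- function(a, b) {
  ut <- upper.tri(a$S1)
  sum(a$S1[ut] != b$S1[ut]) + sum(a$S2[ut] != b$S2[ut])
}

support_n_labeled <- function(a) {
  ut <- upper.tri(a$S1)
  sum(a$S1[ut]) + sum(a$S2[ut])
}

support_n_differential <- function(a) {
  ut <- upper.tri(a$S1)
  sum(a$S1[ut] != a$S2[ut])
}

#' Select the fusion penalty by differential-edge significance
#'
#' Permutation calibration of `lambda2`: the two conditions' samples are
#' pooled and re-split `B` times into pseudo-conditions of the original
#' sizes (each pseudo-condition re-standardized), the network is fit on
#' every pseudo-split over a candidate grid, and the smallest candidate is
#' returned for which the expected number of differential edges under this
#' null, divided by the number of differential edges detected on the real
#' split (or 1 if none), is at most `alpha2`. Deterministic given `seed`.
#'
#' @param data A [kddn_data].
#' @param knowledge A [kddn_prior] or `NULL`.
#' @param lambda1 The already-selected sparsity penalty.
#' @param theta Knowledge weight to fit at (0 ignores the prior).
#' @param alpha2 Target significance level for differential edges.
#' @param B Number of pseudo-splits, at least 20.
#' @param grid Candidate values; defaults to [lambda2_grid()] of size
#'   `n_grid`.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @param seed Optional integer seed.
#' @param tol,max_iter Solver controls.
#' @return The selected `lambda2` with attributes `"null_rate"` (per-grid
#'   expected null differential count) and `"real_differential"`.
#' @export
select_lambda2 <- function(data, knowledge = NULL, lambda1, theta = 0,
                           alpha2 = 0.05, B = 50, grid = NULL, n_grid = 20,
                           seed = NULL, tol = 1e-6, max_iter = 1000L) {
  data <- ensure_standardized(data)
  if (B < 20) stop("B must be at least 20 for a stable calibration",
                   call. = FALSE)
  genes <- data$genes
  if (is.null(knowledge)) knowledge <- empty_prior(genes)
  knowledge <- align_prior(knowledge, genes)
  if (is.null(grid)) grid <- lambda2_grid(lambda1, n_grid)
  grid <- sort(grid)
  n1 <- nrow(data$X1)
  n2 <- nrow(data$X2)
  pool <- rbind(data$X1, data$X2)

  sm <- scaled_matrices(data)
  real_diff <- vapply(grid, function(l2) {
    support_n_differential(
      fit_supports(sm$X1, sm$X2, knowledge$W, lambda1, theta, l2,
                   tol, max_iter))
  }, numeric(1))

  null_counts <- with_seed_or_not(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n1 + n2, n1)
      pd <- standardize(kddn_data(pool[idx, , drop = FALSE],
                                  pool[-idx, , drop = FALSE],
                                  genes = genes))
      psm <- scaled_matrices(pd)
      vapply(grid, function(l2) {
        support_n_differential(
          fit_supports(psm$X1, psm$X2, knowledge$W, lambda1, theta, l2,
                       tol, max_iter))
      }, numeric(1))
    }, numeric(length(grid)))
  })
  null_mean <- rowMeans(matrix(null_counts, nrow = length(grid)))
  rate <- null_mean / pmax(1, real_diff)
  ok <- which(rate <= alpha2)
  if (length(ok) == 0L) {
    warning("no grid value reaches alpha2 = ", alpha2,
            "; returning the largest candidate", call. = FALSE)
    sel <- length(grid)
  } else {
    sel <- ok[1]
  }
  structure(grid[sel], null_rate = null_mean, real_differential = real_diff,
            grid = grid)
}

#' Calibrate the knowledge weight against random knowledge
#'
#' Worst-case calibration of `theta`: for each grid value, `R` completely
#' random priors with `M` edges are drawn, the network is refit with each,
#' and the relative graph edit distance to the data-only network
#' \eqn{d(G_X, G_{X,W_R,\theta}) / |E_X|} is averaged. The selected
#' \eqn{\hat\theta} is the largest grid value whose mean relative distance
#' is at most `delta`; `theta = 0` gives distance exactly 0, so a value
#' always exists. One common set of random draws is reused across the grid
#' (common random numbers reduce Monte-Carlo variance of the comparison).
#'
#' @param data A [kddn_data].
#' @param M Number of knowledge edges per random draw; defaults to the
#'   number of distinct pairs in the data-only network.
#' @param params A [kddn_params] with `lambda1`, `lambda2` and `delta`
#'   fixed (`lambda1 = NULL` is selected first).
#' @param grid Ascending theta grid in `[0, 1]`.
#' @param R Random-knowledge draws per grid value.
#' @param seed Optional integer seed; identical seeds give identical
#'   calibrations.
#' @param tol,max_iter Solver controls.
#'
#' @return An object of class `kddn_theta_calibration`: `$theta_hat`, the
#'   calibration table `$table` (theta, mean/sd relative distance,
#'   feasibility), `$n_edges_gx` (labeled edge count of the data-only
#'   network) and `$distances` (the per-draw matrix).
#' @export
select_theta <- function(data, M = NULL, params = kddn_params(),
                         grid = seq(0, 1, by = 0.1), R = 100, seed = NULL,
                         tol = 1e-6, max_iter = 1000L) {
  data <- ensure_standardized(data)
  stopifnot(inherits(params, "kddn_params"))
  if (is.null(params$lambda1)) {
    params$lambda1 <- select_lambda1(data, alpha1 = params$alpha1)
  }
  if (is.null(params$lambda2)) {
    stop("lambda2 must be fixed before calibrating theta; ",
         "run select_lambda2() first", call. = FALSE)
  }
  grid <- sort(unique(c(0, grid)))
  if (any(grid < 0 | grid > 1)) stop("theta grid must lie in [0, 1]",
                                     call. = FALSE)
  p <- length(data$genes)
  sm <- scaled_matrices(data)
  W0 <- matrix(0, p, p)
  gx <- fit_supports(sm$X1, sm$X2, W0, params$lambda1, 0, params$lambda2,
                     tol, max_iter)
  n_ex <- support_n_labeled(gx)
  if (n_ex == 0L) {
    stop("empty data-driven network; cannot calibrate theta", call. = FALSE)
  }
  ut <- upper.tri(gx$S1)
  n_pairs_gx <- sum(gx$S1[ut] | gx$S2[ut])
  if (is.null(M)) M <- n_pairs_gx
  if (M < 0) stop("M must be non-negative", call. = FALSE)

  draw_seeds <- with_seed_or_not(seed,
    sample.int(.Machine$integer.max, R))
  priors <- lapply(draw_seeds, function(s)
    sample_random_knowledge(p, M, seed = s, genes = data$genes))

  dist_mat <- matrix(0, nrow = R, ncol = length(grid),
                     dimnames = list(NULL, as.character(grid)))
  for (k in seq_along(grid)) {
    th <- grid[k]
    if (th == 0) next   # identical to the data-only fit by construction
    dist_mat[, k] <- vapply(priors, function(pr) {
      fit <- fit_supports(sm$X1, sm$X2, pr$W, params$lambda1, th,
                          params$lambda2, tol, max_iter)
      support_distance(gx, fit) / n_ex
    }, numeric(1))
  }
  means <- unname(colMeans(dist_mat))
  sds <- unname(apply(dist_mat, 2, sd))
  feasible <- means <= params$delta
  theta_hat <- max(grid[feasible])
  structure(
    list(theta_hat = theta_hat,
         table = tibble::tibble(theta = grid, mean_distance = means,
                                sd_distance = sds, feasible = feasible),
         delta = params$delta, M = M, R = R,
         n_edges_gx = n_ex, lambda1 = params$lambda1,
         lambda2 = params$lambda2, distances = dist_mat),
    class = "kddn_theta_calibration"
  )
}

#' @export
print.kddn_theta_calibration <- function(x, ...) {
  cat("<kddn_theta_calibration> theta_hat = ", x$theta_hat,
      " (delta = ", x$delta, ", M = ", x$M, ", R = ", x$R, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @method tidy kddn_theta_calibration
#' @export
tidy.kddn_theta_calibration <- function(x, ...) x$table

#' @method glance kddn_theta_calibration
#' @export
glance.kddn_theta_calibration <- function(x, ...) {
  tibble::tibble(theta_hat = x$theta_hat, delta = x$delta, M = x$M,
                 R = x$R, n_edges_gx = x$n_edges_gx,
                 lambda1 = x$lambda1, lambda2 = x$lambda2)
}
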