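#' Exact closed-form update for one coefficient pair
#'
#' Minimizes the two-coordinate subproblem that block coordinate descent
#' solves for each gene pair,
#' \deqn{g(b_1, b_2) = \tfrac{1}{2} a_1 b_1^2 - c_1 b_1 +
#'   \tfrac{1}{2} a_2 b_2^2 - c_2 b_2 + w (|b_1| + |b_2|) +
#'   \lambda_2 |b_1 - b_2|,}
#' where \eqn{c_k} is the inner product of condition-\eqn{k}'s partial
#' residual with its design column and \eqn{a_k} that column's squared
#' norm. The solution is exact: the fused candidate (\eqn{b_1 = b_2} with
#' combined penalty \eqn{2w}) and the two sign-pattern candidates
#' (per-coordinate soft-thresholding at \eqn{w} with a \eqn{\pm\lambda_2}
#' tilt) are enumerated and the feasible one with smallest objective is
#' returned. Ties within `1e-12` prefer the fused candidate.
#'
#' @param c1,c2 Partial-residual inner products for the two conditions.
#' @param a1,a2 Positive squared column norms.
#' @param w Non-negative lasso weight, `lambda1 * (1 - W[j,i] * theta)`.
#' @param lambda2 Non-negative fusion penalty.
#'
#' @return Numeric vector `c(b1, b2)`, the exact global minimizer.
#' @examples
#' pair_update(2, -1, 1, 1, w = 0.5, lambda2 = 0)   # decoupled soft-thresholds
#' pair_update(1, 0.8, 1, 1, w = 0.2, lambda2 = 0.5) # fused
#' @export
pair_update <- function(c1, c2, a1, a2, w, lambda2) {
  if (!is.finite(a1) || !is.finite(a2) || a1 <= 0 || a2 <= 0) {
    stop("a1 and a2 must be positive", call. = FALSE)
  }
  pair_update_cpp(c1, c2, a1, a2, w, lambda2)
}

# Build a node problem: the stacked response and the two internally scaled
# design matrices for node i (the beta_ii = 0 constraint is enforced by
# excluding coordinate i from the coordinate sweep, not by penalizing it).
node_problem <- function(data, i) {
  data <- ensure_standardized(data)
  p <- length(data$genes)
  if (is.character(i)) i <- match(i, data$genes)
  if (is.na(i) || i < 1 || i > p) stop("node index out of range", call. = FALSE)
  sm <- scaled_matrices(data)
  structure(
    list(i = as.integer(i), gene = data$genes[i],
         y = c(sm$X1[, i], sm$X2[, i]),
         X1 = sm$X1, X2 = sm$X2,
         beta = NULL, iters = NA_integer_, converged = NA),
    class = "kddn_node"
  )
}

#' @export
print.kddn_node <- function(x, ...) {
  cat("<kddn_node> node ", x$i, " (", x$gene, ")",
      if (!is.null(x$beta)) paste0("; solved in ", x$iters, " sweep(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Objective value of the joint node regression
#'
#' Evaluates the per-node objective
#' \deqn{f(\beta) = \tfrac{1}{2}\|y - X\beta\|_2^2 +
#'   \lambda_1 \sum_j (1 - W_{ji}\theta)(|\beta_{ji}^{(1)}| + |\beta_{ji}^{(2)}|) +
#'   \lambda_2 \sum_j |\beta_{ji}^{(1)} - \beta_{ji}^{(2)}|}
#' on the node problem's own stacked response and block-diagonal design.
#'
#' @param problem A `kddn_node` (from [fit_node()] or internal
#'   construction), holding `y`, the per-condition design blocks and
#'   optionally a solution.
#' @param knowledge_col 0/1 vector of length p: column `i` of the prior
#'   adjacency.
#' @param params A [kddn_params] with fixed `lambda1`, `lambda2`, `theta`.
#' @param beta Optional p x 2 coefficient matrix to evaluate; defaults to
#'   the problem's stored solution (or all zeros if unsolved).
#'
#' @return Non-negative scalar objective value.
#' @export
objective_value <- function(problem, knowledge_col, params, beta = NULL) {
  stopifnot(inherits(problem, "kddn_node"), inherits(params, "kddn_params"))
  p <- ncol(problem$X1)
  if (length(knowledge_col) != p) {
    stop("knowledge_col must have length p = ", p, call. = FALSE)
  }
  if (is.null(beta)) beta <- problem$beta
  if (is.null(beta)) beta <- matrix(0, p, 2)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(p, 2))) stop("beta must be p x 2", call. = FALSE)
  if (any(beta[problem$i, ] != 0)) {
    stop("beta_ii must be zero", call. = FALSE)
  }
  n1 <- nrow(problem$X1)
  r <- problem$y - c(problem$X1 %*% beta[, 1], problem$X2 %*% beta[, 2])
  wts <- 1 - knowledge_col * params$theta
  0.5 * sum(r^2) +
    params$lambda1 * sum(wts * (abs(beta[, 1]) + abs(beta[, 2]))) +
    params$lambda2 * sum(abs(beta[, 1] - beta[, 2]))
}

#' Solve one node's joint regression by block coordinate descent
#'
#' Cycles over coordinate pairs `j != i` in fixed order, applying
#' [pair_update()] to each with current partial residuals, until the
#' largest absolute coefficient change in a full sweep falls below `tol`.
#' The objective is non-increasing at every block update because each
#' update is the exact minimizer of its subproblem.
#'
#' @param i Node index (or gene name).
#' @param data A [kddn_data]; standardized internally if needed.
#' @param knowledge A [kddn_prior] or `NULL` (no prior).
#' @param params A [kddn_params] with `lambda1`, `lambda2`, `theta` set.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param max_iter Maximum number of full sweeps.
#' @param trace Record the objective value after every sweep (in
#'   `$objective_trace`).
#'
#' @return The solved `kddn_node`: `$beta` is the p x 2 coefficient matrix
#'   (columns = conditions, row `i` fixed at zero), with `$iters`,
#'   `$converged` and optionally `$objective_trace`.
#' @export
fit_node <- function(i, data, knowledge = NULL, params = kddn_params(),
                     tol = 1e-6, max_iter = 1000L, trace = FALSE) {
  data <- ensure_standardized(data)
  prob <- node_problem(data, i)
  p <- length(data$genes)
  if (is.null(knowledge)) knowledge <- empty_prior(data$genes)
  stopifnot(inherits(knowledge, "kddn_prior"), inherits(params, "kddn_params"))
  if (is.null(params$lambda1) || is.null(params$lambda2)) {
    stop("lambda1 and lambda2 must be fixed before fitting", call. = FALSE)
  }
  w <- params$lambda1 * (1 - knowledge$W[, prob$i] * params$theta)
  res <- bcd_node_cpp(prob$X1, prob$X2, prob$i, w, params$lambda2,
                      tol, as.integer(max_iter), trace,
                      numeric(p), numeric(p))
  if (!res$converged) {
    stop("node ", prob$i, " (", prob$gene, ") did not converge in ",
         max_iter, " sweeps (last change ", format(res$last_delta),
         ")", call. = FALSE)
  }
  prob$beta <- cbind(cond1 = as.numeric(res$beta1),
                     cond2 = as.numeric(res$beta2))
  rownames(prob$beta) <- data$genes
  prob$iters <- res$iters
  prob$converged <- res$converged
  if (trace) prob$objective_trace <- as.numeric(res$objective_trace)
  prob
}
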