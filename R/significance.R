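#' Permutation p-value for one differential edge
#'
#' Tests a detected differential edge by condition-label permutation. The
#' observed statistic is the coefficient-difference sum over both
#' regression directions,
#' \deqn{T = |\hat\beta_{ji}^{(1)} - \hat\beta_{ji}^{(2)}| +
#'          |\hat\beta_{ij}^{(1)} - \hat\beta_{ij}^{(2)}|,}
#' from the full fit. The null distribution is obtained by pooling the two
#' conditions' samples, re-splitting them `B` times at the original sample
#' sizes and refitting only the two node problems that touch the edge
#' (node problems are independent, so this reproduces the full-network
#' coefficients for those nodes; set `refit = "network"` for a full-network
#' refit). The add-one estimate
#' `pvalue = (1 + #\{T_perm >= T_obs\}) / (B + 1)` avoids zero p-values.
#'
#' @param data A [kddn_data].
#' @param edge Length-2 vector of gene names or indices.
#' @param params A [kddn_params] with `lambda1` and `lambda2` fixed.
#' @param knowledge A [kddn_prior] or `NULL`.
#' @param B Number of permutations, at least 19.
#' @param seed Optional integer seed.
#' @param check_differential Error unless the edge is differential in the
#'   observed fit (set to `FALSE` to test any edge).
#' @param refit `"nodes"` (default, refit the two touched node problems)
#'   or `"network"`.
#' @param tol,max_iter Solver controls.
#'
#' @return A one-row tibble: `node_a`, `node_b`, `statistic`, `pvalue`,
#'   `B`.
#' @export
differential_edge_pvalue <- function(data, edge, params, knowledge = NULL,
                                     B = 199, seed = NULL,
                                     check_differential = TRUE,
                                     refit = c("nodes", "network"),
                                     tol = 1e-6, max_iter = 1000L) {
  refit <- match.arg(refit)
  data <- ensure_standardized(data)
  if (B < 19) stop("B must be at least 19", call. = FALSE)
  stopifnot(inherits(params, "kddn_params"))
  if (is.null(params$lambda1) || is.null(params$lambda2)) {
    stop("lambda1 and lambda2 must be fixed", call. = FALSE)
  }
  genes <- data$genes
  if (is.character(edge)) edge <- match(edge, genes)
  edge <- as.integer(edge)
  if (length(edge) != 2 || any(is.na(edge)) || edge[1] == edge[2]) {
    stop("`edge` must name two distinct genes", call. = FALSE)
  }
  edge <- sort(edge)
  if (is.null(knowledge)) knowledge <- empty_prior(genes)
  knowledge <- align_prior(knowledge, genes)

  edge_stat <- function(d) {
    sm <- scaled_matrices(d)
    if (refit == "network") {
      res <- fit_network_cpp(sm$X1, sm$X2, knowledge$W, params$lambda1,
                             params$theta, params$lambda2, tol,
                             as.integer(max_iter))
      B1 <- res$B1
      B2 <- res$B2
      list(stat = abs(B1[edge[1], edge[2]] - B2[edge[1], edge[2]]) +
             abs(B1[edge[2], edge[1]] - B2[edge[2], edge[1]]),
           S1 = {S <- B1 != 0; S | t(S)},
           S2 = {S <- B2 != 0; S | t(S)})
    } else {
      p <- length(genes)
      stat <- 0
      sup <- list()
      for (i in edge) {
        w <- params$lambda1 * (1 - knowledge$W[, i] * params$theta)
        r <- bcd_node_cpp(sm$X1, sm$X2, i, w, params$lambda2, tol,
                          as.integer(max_iter), FALSE, numeric(p), numeric(p))
        if (!r$converged) stop("node ", i, " did not converge", call. = FALSE)
        j <- setdiff(edge, i)
        stat <- stat + abs(r$beta1[j] - r$beta2[j])
        sup[[as.character(i)]] <- c(b1 = r$beta1[j], b2 = r$beta2[j])
      }
      in1 <- any(vapply(sup, function(s) s["b1"] != 0, logical(1)))
      in2 <- any(vapply(sup, function(s) s["b2"] != 0, logical(1)))
      list(stat = stat, in1 = in1, in2 = in2)
    }
  }

  obs <- edge_stat(data)
  if (check_differential) {
    is_diff <- if (refit == "network") {
      xor(obs$S1[edge[1], edge[2]], obs$S2[edge[1], edge[2]])
    } else {
      xor(obs$in1, obs$in2)
    }
    if (!is_diff) {
      stop("edge (", genes[edge[1]], ", ", genes[edge[2]],
           ") is not differential; set check_differential = FALSE to test anyway",
           call. = FALSE)
    }
  }

  n1 <- nrow(data$X1)
  n2 <- nrow(data$X2)
  pool <- rbind(data$X1, data$X2)
  t_perm <- with_seed_or_not(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n1 + n2, n1)
      pd <- standardize(kddn_data(pool[idx, , drop = FALSE],
                                  pool[-idx, , drop = FALSE],
                                  genes = genes))
      edge_stat(pd)$stat
    }, numeric(1))
  })
  pval <- (1 + sum(t_perm >= obs$stat)) / (B + 1)
  tibble::tibble(node_a = genes[edge[1]], node_b = genes[edge[2]],
                 statistic = obs$stat, pvalue = pval, B = as.integer(B))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate adjustment (a thin wrapper around
#' [stats::p.adjust()] kept for a stable surface in edge tables).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`; an empty vector
#'   returns an empty vector.
#' @return Adjusted q-values, order-preserving.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Attach permutation p-values to a fitted network's differential edges
#'
#' Runs [differential_edge_pvalue()] for every differential edge of the
#' fit and fills the `pvalue` and BH-adjusted `qvalue` columns of the edge
#' table. Common edges keep `NA`.
#'
#' @param fit A `kddn_fit` (which carries its data and parameters).
#' @param knowledge A [kddn_prior] or `NULL` (defaults to no prior, as in
#'   the fit when none was supplied).
#' @param B Permutations per edge.
#' @param seed Optional integer seed (per-edge seeds are derived from it).
#' @param ... Passed on to [differential_edge_pvalue()].
#' @return The fit with `pvalue`/`qvalue` filled in `$edges`.
#' @export
edge_significance <- function(fit, knowledge = NULL, B = 199, seed = NULL,
                              ...) {
  stopifnot(inherits(fit, "kddn_fit"))
  diff_idx <- which(fit$edges$condition != "both")
  if (length(diff_idx) == 0L) return(fit)
  edge_seeds <- with_seed_or_not(seed,
    sample.int(.Machine$integer.max, length(diff_idx)))
  pvals <- purrr::map2_dbl(diff_idx, edge_seeds, function(k, s) {
    differential_edge_pvalue(
      fit$data, edge = c(fit$edges$node_a[k], fit$edges$node_b[k]),
      params = fit$params, knowledge = knowledge, B = B, seed = s,
      check_differential = FALSE, ...)$pvalue
  })
  fit$edges$pvalue[diff_idx] <- pvals
  fit$edges$qvalue[diff_idx] <- adjust_fdr(pvals)
  fit
}
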