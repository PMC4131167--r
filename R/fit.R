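#' Fit the pair of condition-specific dependency networks
#'
#' Solves the joint node regression for every node and assembles the two
#' condition-specific edge sets. An edge `(i, j)` is present in condition
#' `c` if either node's regression selects the other (OR symmetrization,
#' the neighborhood-selection convention; set `symmetrize = "and"` for the
#' stricter rule). Edges present in exactly one condition form the
#' differential dependency network.
#'
#' @param data A [kddn_data]; standardized internally if needed.
#' @param knowledge A [kddn_prior] or `NULL`. With `theta = 0` the content
#'   of the prior has no effect on the result.
#' @param params A [kddn_params]. `lambda1`/`lambda2` that are `NULL` are
#'   selected by [select_lambda1()] / [select_lambda2()] first.
#' @param symmetrize `"or"` (default) or `"and"`.
#' @param tol,max_iter Block coordinate descent controls (see
#'   [fit_node()]).
#' @param seed Seed forwarded to [select_lambda2()] when the fusion penalty
#'   has to be selected here.
#'
#' @return An object of class `kddn_fit` with the edge table (`$edges`, a
#'   tibble; see [tidy.kddn_fit()]), the full coefficient matrices `$beta1`
#'   and `$beta2` (entry `[j, i]` is gene j's coefficient in gene i's
#'   regression), the parameters used, and per-node sweep counts.
#' @examples
#' truth <- perturb_network(simulate_gmrf_truth(20, seed = 1), seed = 2)
#' d <- sample_condition_data(truth, 60, seed = 3)
#' fit <- kddn_fit(d, params = kddn_params(lambda1 = 0.6, lambda2 = 0.05))
#' glance(fit)
#' @export
kddn_fit <- function(data, knowledge = NULL, params = kddn_params(),
                     symmetrize = c("or", "and"), tol = 1e-6,
                     max_iter = 1000L, seed = NULL) {
  symmetrize <- match.arg(symmetrize)
  data <- ensure_standardized(data)
  genes <- data$genes
  p <- length(genes)
  if (is.null(knowledge)) knowledge <- empty_prior(genes)
  knowledge <- align_prior(knowledge, genes)
  stopifnot(inherits(params, "kddn_params"))
  if (is.null(params$lambda1)) {
    params$lambda1 <- select_lambda1(data, alpha1 = params$alpha1)
  }
  if (is.null(params$lambda2)) {
    params$lambda2 <- select_lambda2(data, knowledge,
                                     lambda1 = params$lambda1,
                                     theta = params$theta,
                                     alpha2 = params$alpha2, seed = seed)
  }
  sm <- scaled_matrices(data)
  res <- fit_network_cpp(sm$X1, sm$X2, knowledge$W, params$lambda1,
                         params$theta, params$lambda2, tol,
                         as.integer(max_iter))
  if (!all(res$converged)) {
    bad <- which(!res$converged)[1]
    stop("node ", bad, " (", genes[bad], ") did not converge in ",
         max_iter, " sweeps (last change ",
         format(res$last_delta[bad]), ")", call. = FALSE)
  }
  B1 <- res$B1
  B2 <- res$B2
  dimnames(B1) <- dimnames(B2) <- list(genes, genes)
  structure(
    list(edges = assemble_edges(B1, B2, genes, symmetrize),
         beta1 = B1, beta2 = B2, genes = genes, params = params,
         symmetrize = symmetrize,
         n1 = nrow(data$X1), n2 = nrow(data$X2),
         sweeps = as.integer(res$iters),
         scales = data$scales,
         data = data),
    class = "kddn_fit"
  )
}

# Edge table from the two coefficient matrices. beta*_ab is the coefficient
# of node_a in node_b's regression (direction a -> b) for condition *.
assemble_edges <- function(B1, B2, genes, symmetrize = "or") {
  comb <- if (symmetrize == "or") `|` else `&`
  S1 <- comb(B1 != 0, t(B1) != 0)
  S2 <- comb(B2 != 0, t(B2) != 0)
  ut <- upper.tri(S1)
  keep <- which(ut & (S1 | S2), arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(tibble::tibble(
      node_a = character(), node_b = character(),
      condition = character(),
      beta1_ab = numeric(), beta2_ab = numeric(),
      beta1_ba = numeric(), beta2_ba = numeric(),
      pvalue = numeric(), qvalue = numeric()))
  }
  a <- keep[, 1]
  b <- keep[, 2]
  in1 <- S1[keep]
  in2 <- S2[keep]
  tibble::tibble(
    node_a = genes[a], node_b = genes[b],
    condition = dplyr::case_when(in1 & in2 ~ "both", in1 ~ "cond1",
                                 TRUE ~ "cond2"),
    beta1_ab = B1[cbind(a, b)], beta2_ab = B2[cbind(a, b)],
    beta1_ba = B1[cbind(b, a)], beta2_ba = B2[cbind(b, a)],
    pvalue = NA_real_, qvalue = NA_real_
  )
}

#' @export
print.kddn_fit <- function(x, ...) {
  g <- glance(x)
  cat("<kddn_fit> ", g$p, " genes; |E1| = ", g$n_edges_cond1,
      ", |E2| = ", g$n_edges_cond2, "; common = ", g$n_common,
      ", differential = ", g$n_differential, "\n", sep = "")
  cat("  lambda1 = ", format(g$lambda1, digits = 4),
      ", lambda2 = ", format(g$lambda2, digits = 4),
      ", theta = ", format(g$theta, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the fitted network pair into its edge table
#'
#' @param x A `kddn_fit`.
#' @param scale `"standardized"` reports coefficients on the unit-variance
#'   scale the model is fit on; `"original"` rescales each directed
#'   coefficient by the response/predictor standard deviation ratio of its
#'   condition.
#' @param ... Unused.
#' @return A tibble with one row per edge: `node_a`, `node_b` (canonical
#'   order), `condition` (`cond1`/`cond2`/`both`), the four directed
#'   coefficients, and `pvalue`/`qvalue` when [edge_significance()] has
#'   been run.
#' @method tidy kddn_fit
#' @export
tidy.kddn_fit <- function(x, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  edges <- x$edges
  if (scale == "original" && !is.null(x$scales)) {
    s1 <- x$scales$cond1
    s2 <- x$scales$cond2
    ratio <- function(s, from, to) s[to] / s[from]
    edges <- dplyr::mutate(
      edges,
      beta1_ab = .data$beta1_ab * ratio(s1, .data$node_a, .data$node_b),
      beta2_ab = .data$beta2_ab * ratio(s2, .data$node_a, .data$node_b),
      beta1_ba = .data$beta1_ba * ratio(s1, .data$node_b, .data$node_a),
      beta2_ba = .data$beta2_ba * ratio(s2, .data$node_b, .data$node_a)
    )
  }
  edges
}

#' One-row summary of a fitted network pair
#'
#' @param x A `kddn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, sample sizes, the three
#'   regularization parameters, per-condition edge counts, common and
#'   differential edge counts, and the largest per-node sweep count.
#' @method glance kddn_fit
#' @export
glance.kddn_fit <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    p = length(x$genes), n1 = x$n1, n2 = x$n2,
    lambda1 = x$params$lambda1, lambda2 = x$params$lambda2,
    theta = x$params$theta,
    n_edges_cond1 = sum(e$condition != "cond2"),
    n_edges_cond2 = sum(e$condition != "cond1"),
    n_common = sum(e$condition == "both"),
    n_differential = sum(e$condition != "both"),
    max_sweeps = if (length(x$sweeps)) max(x$sweeps) else NA_integer_
  )
}

#' Extract condition-labeled edge sets
#'
#' Canonical labeled representation used for graph edit distance and
#' scoring: a tibble of `(node_a, node_b, condition)` with `node_a <
#' node_b`, where a common edge is listed once with `condition = "both"`.
#'
#' @param x A `kddn_fit`, two-condition `kddn_truth`, or an edge tibble
#'   already in this shape.
#' @param ... Unused.
#' @return A tibble with columns `node_a`, `node_b`, `condition`.
#' @export
as_edge_table <- function(x, ...) UseMethod("as_edge_table")

#' @export
as_edge_table.kddn_fit <- function(x, ...) {
  dplyr::select(x$edges, "node_a", "node_b", "condition")
}

#' @export
as_edge_table.data.frame <- function(x, ...) {
  stopifnot(all(c("node_a", "node_b", "condition") %in% names(x)))
  swap <- x$node_a > x$node_b
  out <- tibble::as_tibble(x)[, c("node_a", "node_b", "condition")]
  tmp <- out$node_a[swap]
  out$node_a[swap] <- out$node_b[swap]
  out$node_b[swap] <- tmp
  out
}
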