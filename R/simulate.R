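#' Generate a sparse Gaussian Markov random field ground truth
#'
#' Constructs a random geometric-flavoured sparse graph and its precision
#' matrix: `p` nodes are placed uniformly at random in the unit square and
#' each pair is connected with probability \eqn{\phi(d\sqrt{p})} (standard
#' normal density of the scaled Euclidean distance), rejecting edges that
#' would push either endpoint past `degree_cap`. The precision matrix has
#' unit diagonal and value `partial` at every edge; if its smallest
#' eigenvalue falls below 0.05 it is diagonally loaded and rescaled back to
#' unit diagonal, which preserves the support exactly.
#'
#' @param p Number of nodes, at least 10.
#' @param seed Optional integer seed; the construction is a pure function
#'   of it.
#' @param degree_cap Maximum node degree.
#' @param partial Off-diagonal precision value at edges (approximately the
#'   negative partial correlation); `0` gives the identity and no edges.
#'
#' @return An object of class `kddn_truth` with one condition: `genes`,
#'   `edges1` (two-column matrix of gene-index pairs, `a < b`), `Omega1`,
#'   node coordinates and generation settings.
#' @examples
#' tr <- simulate_gmrf_truth(30, seed = 1)
#' nrow(tr$edges1)
#' @export
simulate_gmrf_truth <- function(p, seed = NULL, degree_cap = 4,
                                partial = 0.245) {
  if (p < 10) stop("p must be at least 10", call. = FALSE)
  with_seed_or_not(seed, {
    pts <- cbind(runif(p), runif(p))
    d <- as.matrix(dist(pts))
    prob <- dnorm(d * sqrt(p))
    diag(prob) <- 0
    deg <- integer(p)
    edges <- matrix(integer(0), 0, 2)
    pairs <- which(upper.tri(prob), arr.ind = TRUE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    accept <- runif(nrow(pairs)) < prob[pairs]
    for (k in which(accept)) {
      a <- pairs[k, 1]
      b <- pairs[k, 2]
      if (deg[a] < degree_cap && deg[b] < degree_cap) {
        edges <- rbind(edges, c(min(a, b), max(a, b)))
        deg[a] <- deg[a] + 1
        deg[b] <- deg[b] + 1
      }
    }
    if (partial == 0) edges <- matrix(integer(0), 0, 2)
    genes <- sprintf("g%03d", seq_len(p))
    structure(
      list(p = p, genes = genes, conditions = 1L,
           edges1 = canonical_edges(edges),
           Omega1 = precision_from_edges(p, edges, partial),
           coords = pts,
           settings = list(degree_cap = degree_cap, partial = partial,
                           seed = seed)),
      class = "kddn_truth"
    )
  })
}

canonical_edges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0L) return(edges[order(integer(0)), , drop = FALSE])
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Unit-diagonal precision matrix with `partial` at the given edges,
# diagonally loaded and renormalized if needed; the repair only rescales,
# so the support equals the edge set exactly.
precision_from_edges <- function(p, edges, partial) {
  om <- diag(p)
  if (nrow(edges) > 0 && partial != 0) {
    om[edges] <- partial
    om[edges[, c(2, 1), drop = FALSE]] <- partial
  }
  ev <- min(eigen(om, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) {
    om <- om + (0.05 - ev + 1e-9) * diag(p)
    dm <- 1 / sqrt(diag(om))
    om <- om * tcrossprod(dm)
  }
  om
}

#' Rewire a fraction of edges to create the second condition
#'
#' Condition 1 keeps the original graph. For condition 2,
#' \eqn{\lceil f |E| \rceil} randomly chosen edges are deleted and the same
#' number of new random edges (respecting the degree cap) are inserted, so
#' the rewiring is balanced and the symmetric difference of the two edge
#' sets has exactly \eqn{2\lceil f |E| \rceil} pairs. Both precision
#' matrices are rebuilt with the same off-diagonal value and
#' positive-definite repair as in [simulate_gmrf_truth()].
#'
#' @param truth A single-condition `kddn_truth`.
#' @param rewire_fraction Fraction of edges to rewire, in (0, 1).
#' @param seed Optional integer seed.
#' @return A two-condition `kddn_truth`: adds `edges2`, `Omega2`, and the
#'   partition `E_common`, `E1_only`, `E2_only`.
#' @examples
#' tr <- perturb_network(simulate_gmrf_truth(30, seed = 1), 0.1, seed = 2)
#' nrow(tr$E1_only) == nrow(tr$E2_only)
#' @export
perturb_network <- function(truth, rewire_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(truth, "kddn_truth"))
  if (truth$conditions != 1L) {
    stop("`truth` already has two conditions", call. = FALSE)
  }
  if (rewire_fraction <= 0 || rewire_fraction >= 1) {
    stop("rewire_fraction must be in (0, 1)", call. = FALSE)
  }
  p <- truth$p
  e1 <- truth$edges1
  n_e <- nrow(e1)
  k <- ceiling(rewire_fraction * n_e)
  if (k == 0L) stop("no edges to rewire", call. = FALSE)
  with_seed_or_not(seed, {
    drop_idx <- sample.int(n_e, k)
    kept <- e1[-drop_idx, , drop = FALSE]
    adj <- matrix(FALSE, p, p)
    adj[e1] <- TRUE
    adj[e1[, c(2, 1), drop = FALSE]] <- TRUE
    deg2 <- tabulate(c(kept), nbins = p)
    cap <- truth$settings$degree_cap
    candidates <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
    candidates <- candidates[sample.int(nrow(candidates)), , drop = FALSE]
    added <- matrix(integer(0), 0, 2)
    for (r in seq_len(nrow(candidates))) {
      if (nrow(added) == k) break
      a <- candidates[r, 1]
      b <- candidates[r, 2]
      if (deg2[a] < cap && deg2[b] < cap) {
        added <- rbind(added, c(a, b))
        deg2[a] <- deg2[a] + 1
        deg2[b] <- deg2[b] + 1
      }
    }
    if (nrow(added) < k) {
      stop("could not place ", k, " new edges under the degree cap",
           call. = FALSE)
    }
    e2 <- canonical_edges(rbind(kept, added))
    truth$edges2 <- e2
    truth$E_common <- canonical_edges(kept)
    truth$E1_only <- canonical_edges(e1[drop_idx, , drop = FALSE])
    truth$E2_only <- canonical_edges(added)
    truth$Omega1 <- precision_from_edges(p, truth$edges1,
                                         truth$settings$partial)
    truth$Omega2 <- precision_from_edges(p, e2, truth$settings$partial)
    truth$conditions <- 2L
    truth$settings$rewire_fraction <- rewire_fraction
    truth$settings$rewire_seed <- seed
    truth
  })
}

#' @export
print.kddn_truth <- function(x, ...) {
  cat("<kddn_truth> p = ", x$p, "; |E1| = ", nrow(x$edges1), sep = "")
  if (x$conditions == 2L) {
    cat("; |E2| = ", nrow(x$edges2), "; common = ", nrow(x$E_common),
        ", rewired = ", nrow(x$E1_only) + nrow(x$E2_only), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Draw multivariate-normal expression samples from the ground truth
#'
#' `n1` and `n2` independent samples with covariance
#' \eqn{\Omega_c^{-1}} per condition; a pure function of `seed`.
#'
#' @param truth A two-condition `kddn_truth`.
#' @param n1,n2 Samples per condition (at least 3 each); `n2` defaults to
#'   `n1`.
#' @param seed Optional integer seed.
#' @return A [kddn_data] over the truth's genes.
#' @export
sample_condition_data <- function(truth, n1, n2 = n1, seed = NULL) {
  stopifnot(inherits(truth, "kddn_truth"))
  if (truth$conditions != 2L) {
    stop("two-condition truth required; run perturb_network() first",
         call. = FALSE)
  }
  if (n1 < 3 || n2 < 3) stop("each condition needs at least 3 samples",
                             call. = FALSE)
  with_seed_or_not(seed, {
    x1 <- MASS::mvrnorm(n1, rep(0, truth$p), solve(truth$Omega1))
    x2 <- MASS::mvrnorm(n2, rep(0, truth$p), solve(truth$Omega2))
    colnames(x1) <- colnames(x2) <- truth$genes
    kddn_data(x1, x2)
  })
}

#' Construct prior knowledge with a controlled false-positive rate
#'
#' Samples `round((1 - fp_rate) * M)` knowledge edges uniformly without
#' replacement from the common true edges and the remainder from pairs
#' that are edges in neither condition (false positives with respect to
#' both ground truths). With `biased = TRUE` the false positives are
#' concentrated on pairs touching a randomly chosen 10% of the nodes.
#'
#' @param truth A two-condition `kddn_truth`.
#' @param M Total number of knowledge edges; defaults to the number of
#'   common true edges.
#' @param fp_rate False-positive rate in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param biased Concentrate false positives on a node subset.
#' @return A [kddn_prior].
#' @export
make_prior_knowledge <- function(truth, M = NULL, fp_rate = 0, seed = NULL,
                                 biased = FALSE) {
  stopifnot(inherits(truth, "kddn_truth"))
  if (truth$conditions != 2L) {
    stop("two-condition truth required", call. = FALSE)
  }
  if (fp_rate < 0 || fp_rate > 1) stop("fp_rate must be in [0, 1]",
                                       call. = FALSE)
  if (is.null(M)) M <- nrow(truth$E_common)
  if (M < 1) stop("M must be at least 1", call. = FALSE)
  n_true <- round((1 - fp_rate) * M)
  n_false <- M - n_true
  if (n_true > nrow(truth$E_common)) {
    stop("requested ", n_true, " true knowledge edges but only ",
         nrow(truth$E_common), " common edges exist", call. = FALSE)
  }
  p <- truth$p
  adj_any <- matrix(FALSE, p, p)
  for (e in list(truth$edges1, truth$edges2)) {
    adj_any[e] <- TRUE
    adj_any[e[, c(2, 1), drop = FALSE]] <- TRUE
  }
  non_edges <- which(upper.tri(adj_any) & !adj_any, arr.ind = TRUE)
  with_seed_or_not(seed, {
    chosen_true <- truth$E_common[sample.int(nrow(truth$E_common), n_true), ,
                                  drop = FALSE]
    pool <- non_edges
    if (biased && n_false > 0) {
      hubs <- sample.int(p, max(1L, ceiling(0.1 * p)))
      touch <- pool[, 1] %in% hubs | pool[, 2] %in% hubs
      if (sum(touch) >= n_false) pool <- pool[touch, , drop = FALSE]
    }
    if (n_false > nrow(pool)) {
      stop("not enough non-edges for ", n_false, " false knowledge edges",
           call. = FALSE)
    }
    chosen_false <- pool[sample.int(nrow(pool), n_false), , drop = FALSE]
    W <- matrix(0, p, p, dimnames = list(truth$genes, truth$genes))
    sel <- rbind(chosen_true, chosen_false)
    if (nrow(sel) > 0) {
      W[sel] <- 1
      W[sel[, c(2, 1), drop = FALSE]] <- 1
    }
    kddn_prior(W, genes = truth$genes, directed = FALSE)
  })
}

# Labeled edge table of the ground truth (condition labels as fit output).
#' @export
as_edge_table.kddn_truth <- function(x, ...) {
  if (x$conditions != 2L) stop("two-condition truth required", call. = FALSE)
  lab <- function(e, cond) {
    tibble::tibble(node_a = x$genes[e[, 1]], node_b = x$genes[e[, 2]],
                   condition = cond)
  }
  dplyr::bind_rows(lab(x$E_common, "both"), lab(x$E1_only, "cond1"),
                   lab(x$E2_only, "cond2"))
}
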