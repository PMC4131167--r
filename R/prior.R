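#' Prior-knowledge network
#'
#' Encode a prior-knowledge network (for example a pathway database
#' rendering) as a binary adjacency matrix over the genes of interest.
#' `W[j, i] = 1` states that prior knowledge supports an edge between gene
#' `j` and gene `i`; during fitting such coordinate pairs have their lasso
#' penalty relaxed by the knowledge weight `theta`.
#'
#' @param x Either a square 0/1 adjacency matrix (with gene identifiers as
#'   dimnames, or conforming to `genes`), or a two-column matrix/data frame
#'   of gene-pair edges.
#' @param genes Character vector of gene identifiers defining the node set
#'   (required for edge-list input; edges touching unknown genes are dropped
#'   with a warning).
#' @param directed Keep the adjacency as given instead of symmetrizing.
#'
#' @return An object of class `kddn_prior`: list with the adjacency `W`,
#'   the `directed` flag, the knowledge edge count `M` (unordered pairs when
#'   undirected, ordered otherwise) and `genes`.
#' @examples
#' pr <- kddn_prior(cbind(a = "g1", b = "g2"), genes = paste0("g", 1:4))
#' pr$M
#' @export
kddn_prior <- function(x, genes = NULL, directed = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x) && ncol(x) == nrow(x) && ncol(x) > 2 &&
      all(x %in% c(0, 1))) {
    W <- x
    storage.mode(W) <- "double"
    if (is.null(genes)) genes <- rownames(W)
    if (is.null(genes)) genes <- paste0("g", seq_len(nrow(W)))
    dimnames(W) <- list(genes, genes)
  } else if (is.matrix(x) && ncol(x) >= 2) {
    if (is.null(genes)) stop("`genes` is required for edge-list input", call. = FALSE)
    p <- length(genes)
    W <- matrix(0, p, p, dimnames = list(genes, genes))
    a <- as.character(x[, 1])
    b <- as.character(x[, 2])
    known <- a %in% genes & b %in% genes
    if (any(!known)) {
      warning(sum(!known), " knowledge edge(s) name unknown genes; dropped",
              call. = FALSE)
    }
    a <- a[known]
    b <- b[known]
    self <- a == b
    if (any(self)) {
      warning(sum(self), " self-loop(s) in knowledge; dropped", call. = FALSE)
      a <- a[!self]
      b <- b[!self]
    }
    W[cbind(a, b)] <- 1
    if (!directed) W[cbind(b, a)] <- 1
  } else if (is.null(x)) {
    if (is.null(genes)) stop("`genes` required", call. = FALSE)
    p <- length(genes)
    W <- matrix(0, p, p, dimnames = list(genes, genes))
  } else {
    stop("`x` must be a square 0/1 adjacency or a two-column edge list",
         call. = FALSE)
  }
  if (!all(W %in% c(0, 1))) stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(diag(W) != 0)) {
    warning("self-loops on the adjacency diagonal; dropped", call. = FALSE)
    diag(W) <- 0
  }
  if (!directed) W <- pmax(W, t(W))
  M <- if (directed) sum(W != 0) else sum(W[upper.tri(W)] != 0)
  structure(
    list(W = W, directed = directed, M = as.integer(M),
         genes = rownames(W)),
    class = "kddn_prior"
  )
}

#' @export
print.kddn_prior <- function(x, ...) {
  cat("<kddn_prior> ", length(x$genes), " genes, M = ", x$M,
      if (x$directed) " directed" else " undirected", " edges\n", sep = "")
  invisible(x)
}

empty_prior <- function(genes) kddn_prior(NULL, genes = genes)

# Restrict/realign a prior to the given gene set, dropping foreign genes.
align_prior <- function(prior, genes) {
  stopifnot(inherits(prior, "kddn_prior"))
  if (identical(prior$genes, genes)) return(prior)
  missing <- setdiff(prior$genes, genes)
  if (length(missing)) {
    warning(length(missing), " prior gene(s) absent from expression data; dropped",
            call. = FALSE)
  }
  p <- length(genes)
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  common <- intersect(prior$genes, genes)
  W[common, common] <- prior$W[common, common]
  kddn_prior(W, genes = genes, directed = prior$directed)
}

#' Sample a completely random prior-knowledge network
#'
#' Draws `M` distinct unordered gene pairs uniformly at random; the
#' zero-information ("random knowledge") prior used to calibrate the
#' knowledge weight in [select_theta()].
#'
#' @param p Number of nodes.
#' @param M Number of knowledge edges, at most `p * (p - 1) / 2`.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param genes Optional gene identifiers (defaults to `g1..gp`).
#'
#' @return A [kddn_prior] with exactly `M` symmetric edges.
#' @examples
#' w <- sample_random_knowledge(10, 5, seed = 1)
#' w$M
#' @export
sample_random_knowledge <- function(p, M, seed = NULL, genes = NULL) {
  n_pairs <- p * (p - 1) / 2
  if (M < 0 || M > n_pairs) {
    stop("M must be between 0 and p(p-1)/2 = ", n_pairs, call. = FALSE)
  }
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  idx <- with_seed_or_not(seed, sample.int(n_pairs, M))
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  if (M > 0) {
    pairs <- pair_from_index(idx, p)
    W[pairs] <- 1
    W[pairs[, c(2, 1), drop = FALSE]] <- 1
  }
  kddn_prior(W, genes = genes, directed = FALSE)
}

# Map linear indices 1..p(p-1)/2 to upper-triangular (i < j) pairs,
# column-major over the upper triangle.
pair_from_index <- function(idx, p) {
  ut <- which(upper.tri(matrix(0, p, p)))
  arr <- arrayInd(ut[idx], c(p, p))
  arr
}
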