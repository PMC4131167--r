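#' Paired two-condition expression data
#'
#' Bundle two expression matrices measured over the same genes under two
#' conditions. Rows are samples, columns are genes; the gene order is shared
#' and enforced. This is the input container for all fitting and calibration
#' functions.
#'
#' @param x1,x2 Numeric matrices (or data frames) of expression values,
#'   samples in rows and genes in columns, one per condition. Column names
#'   are used as gene identifiers when `genes` is not given.
#' @param genes Optional character vector of gene identifiers, overriding
#'   column names. Must have one entry per column.
#'
#' @return An object of class `kddn_data` with elements `genes`, `X1`, `X2`
#'   (matrices, samples x genes) and `standardized` (logical).
#'
#' @details Each condition must contribute at least 3 samples and all values
#'   must be finite. Most downstream functions standardize the data first;
#'   see [standardize()].
#'
#' @examples
#' x1 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
#' x2 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("g", 1:6)))
#' d <- kddn_data(x1, x2)
#' d
#' @export
kddn_data <- function(x1, x2, genes = NULL) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  storage.mode(x1) <- "double"
  storage.mode(x2) <- "double"
  if (ncol(x1) != ncol(x2)) {
    stop("the two conditions must cover the same genes (",
         ncol(x1), " vs ", ncol(x2), " columns)", call. = FALSE)
  }
  p <- ncol(x1)
  if (is.null(genes)) {
    genes <- colnames(x1)
    if (is.null(genes)) genes <- paste0("g", seq_len(p))
  }
  genes <- as.character(genes)
  if (length(genes) != p) stop("`genes` must name every column", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(colnames(x2)) && !identical(colnames(x2), colnames(x1)) &&
      all(colnames(x1) %in% colnames(x2))) {
    # realign condition 2 by gene id when both are named but ordered differently
    x2 <- x2[, colnames(x1), drop = FALSE]
  }
  colnames(x1) <- genes
  colnames(x2) <- genes
  if (nrow(x1) < 3L || nrow(x2) < 3L) {
    stop("each condition needs at least 3 samples", call. = FALSE)
  }
  for (nm in c("x1", "x2")) {
    x <- get(nm)
    if (!all(is.finite(x))) {
      bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
      stop("non-finite value in condition ", if (nm == "x1") 1 else 2,
           " at row ", bad[1], ", gene ", genes[bad[2]], call. = FALSE)
    }
  }
  structure(
    list(genes = genes, X1 = x1, X2 = x2, standardized = FALSE,
         centers = NULL, scales = NULL),
    class = "kddn_data"
  )
}

#' @export
print.kddn_data <- function(x, ...) {
  cat("<kddn_data> ", length(x$genes), " genes; ",
      nrow(x$X1), " + ", nrow(x$X2), " samples",
      if (isTRUE(x$standardized)) " (standardized)", "\n", sep = "")
  invisible(x)
}

n_samples <- function(data) c(nrow(data$X1), nrow(data$X2))

#' Standardize expression columns per condition
#'
#' Centers every gene to mean zero and scales it to unit standard deviation
#' (denominator N - 1), separately within each condition. Scaling factors
#' are kept so that fitted coefficients can be reported on the original
#' scale. Standardizing already-standardized data is a no-op.
#'
#' @param data A [kddn_data] object.
#' @param drop_zero_variance Drop genes with zero variance in either
#'   condition (with a warning) instead of raising an error.
#' @param ... Unused.
#'
#' @return A standardized `kddn_data` with `centers` and `scales` recorded
#'   per condition.
#' @examples
#' d <- kddn_data(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
#' s <- standardize(d)
#' colMeans(s$X1)
#' @export
standardize <- function(data, ...) UseMethod("standardize")

#' @rdname standardize
#' @export
standardize.kddn_data <- function(data, drop_zero_variance = FALSE, ...) {
  if (isTRUE(data$standardized)) return(data)
  sds1 <- apply(data$X1, 2, sd)
  sds2 <- apply(data$X2, 2, sd)
  zero <- sds1 == 0 | sds2 == 0
  if (any(zero)) {
    if (drop_zero_variance) {
      warning("dropping zero variance gene(s): ",
              paste(data$genes[zero], collapse = ", "), call. = FALSE)
      data$X1 <- data$X1[, !zero, drop = FALSE]
      data$X2 <- data$X2[, !zero, drop = FALSE]
      data$genes <- data$genes[!zero]
      sds1 <- sds1[!zero]
      sds2 <- sds2[!zero]
      if (length(data$genes) == 0L) stop("no genes left", call. = FALSE)
    } else {
      stop("zero variance gene(s): ",
           paste(data$genes[zero], collapse = ", "), call. = FALSE)
    }
  }
  mu1 <- colMeans(data$X1)
  mu2 <- colMeans(data$X2)
  data$X1 <- scale(data$X1, center = mu1, scale = sds1)
  data$X2 <- scale(data$X2, center = mu2, scale = sds2)
  attr(data$X1, "scaled:center") <- NULL
  attr(data$X1, "scaled:scale") <- NULL
  attr(data$X2, "scaled:center") <- NULL
  attr(data$X2, "scaled:scale") <- NULL
  data$centers <- list(cond1 = mu1, cond2 = mu2)
  data$scales <- list(cond1 = sds1, cond2 = sds2)
  data$standardized <- TRUE
  data
}

ensure_standardized <- function(data) {
  stopifnot(inherits(data, "kddn_data"))
  if (!isTRUE(data$standardized)) standardize(data) else data
}

# Internally scaled design matrices: standardized columns times sqrt(2/N_c).
# On this scale the half-squared-error objective reproduces the per-sample
# loss convention under which the false-join penalty formula of
# select_lambda1() is derived, so the closed-form lambda1 plugs in directly.
scaled_matrices <- function(data) {
  data <- ensure_standardized(data)
  list(
    X1 = data$X1 * sqrt(2 / nrow(data$X1)),
    X2 = data$X2 * sqrt(2 / nrow(data$X2))
  )
}
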