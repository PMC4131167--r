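# File formats: expression matrices are tab-delimited, first column the
# gene identifier, remaining columns samples (genes in rows). Knowledge is
# a 2/3-column edge list (third column, an interaction type, is ignored)
# or a square 0/1 adjacency with gene ids as header row and first column.

#' Read a two-condition expression pair
#'
#' Either two files (one per condition) or one file plus a two-column
#' condition map (`sample`, `condition`, tab-delimited, conditions taken
#' in sorted order of their labels).
#'
#' @param path First (or only) expression file.
#' @param path2 Second expression file, when the conditions are separate.
#' @param condition_map Path of the sample-to-condition map, when a single
#'   file holds both conditions.
#' @return A [kddn_data].
#' @export
read_expression <- function(path, path2 = NULL, condition_map = NULL) {
  if (is.null(path2) == is.null(condition_map)) {
    stop("supply exactly one of `path2` or `condition_map`", call. = FALSE)
  }
  if (!is.null(path2)) {
    m1 <- read_expression_matrix(path)
    m2 <- read_expression_matrix(path2)
    only1 <- setdiff(rownames(m1), rownames(m2))
    only2 <- setdiff(rownames(m2), rownames(m1))
    if (length(only1) || length(only2)) {
      stop("genes present in only one file: ",
           paste(head(c(only1, only2), 10), collapse = ", "), call. = FALSE)
    }
    m2 <- m2[rownames(m1), , drop = FALSE]
    kddn_data(t(m1), t(m2))
  } else {
    m <- read_expression_matrix(path)
    cm <- utils::read.delim(condition_map, header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(cm) < 2) stop("condition map needs two columns", call. = FALSE)
    names(cm)[1:2] <- c("sample", "condition")
    unknown <- setdiff(cm$sample, colnames(m))
    if (length(unknown)) {
      stop("condition map names unknown sample(s): ",
           paste(head(unknown, 10), collapse = ", "), call. = FALSE)
    }
    conds <- sort(unique(cm$condition))
    if (length(conds) != 2) stop("exactly two conditions required",
                                 call. = FALSE)
    s1 <- cm$sample[cm$condition == conds[1]]
    s2 <- cm$sample[cm$condition == conds[2]]
    kddn_data(t(m[, s1, drop = FALSE]), t(m[, s2, drop = FALSE]))
  }
}

read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing value in ", path, " at gene ", genes[bad[1]],
         ", sample column ", colnames(m)[bad[2]], call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Write a two-condition expression pair
#'
#' @param data A [kddn_data].
#' @param path,path2 Output files, one per condition.
#' @return `data`, invisibly.
#' @export
write_expression <- function(data, path, path2) {
  stopifnot(inherits(data, "kddn_data"))
  wr <- function(x, f) {
    df <- data.frame(gene = data$genes, t(x), check.names = FALSE)
    colnames(df)[-1] <- paste0("s", seq_len(nrow(x)))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(data$X1, path)
  wr(data$X2, path2)
  invisible(data)
}

#' Read a prior-knowledge network
#'
#' Accepts a tab-delimited edge list (two columns, or three with the
#' middle/last interaction type ignored) or a square 0/1 adjacency matrix
#' with gene identifiers as header row and first column. Edges naming
#' genes outside `genes` are dropped with a warning; self-loops are
#' dropped; duplicate edge lines collapse to a single edge.
#'
#' @param path Input file.
#' @param genes Character vector: the expression gene set to restrict to.
#' @param directed Keep direction instead of symmetrizing.
#' @return A [kddn_prior].
#' @export
read_knowledge <- function(path, genes, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_prior(genes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (nf[1] > 3) {
    # adjacency dialect: header row of gene ids, first column gene ids
    df <- utils::read.delim(path, header = TRUE, row.names = 1,
                            check.names = FALSE)
    return(align_prior(kddn_prior(as.matrix(df), directed = directed), genes))
  }
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop("malformed knowledge line ", bad[1], ": ", lines[bad[1]],
         call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1)
  b <- vapply(fields, function(f) f[[length(f)]], "")
  kddn_prior(cbind(a, b), genes = genes, directed = directed)
}

#' Write the fitted edge table
#'
#' Tab-delimited output with columns `node_a`, `node_b`, `condition`,
#' the four directed coefficients, `pvalue` and `qvalue`.
#'
#' @param fit A `kddn_fit`.
#' @param path Output file.
#' @param scale Coefficient scale, see [tidy.kddn_fit()].
#' @return The edge tibble, invisibly.
#' @export
write_edge_table <- function(fit, path,
                             scale = c("standardized", "original")) {
  edges <- tidy(fit, scale = match.arg(scale))
  readr::write_tsv(edges, path)
  invisible(edges)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Input file.
#' @return An edge tibble.
#' @export
read_edge_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    node_a = "c", node_b = "c", condition = "c",
                    .default = "d"))
}

#' Run configuration
#'
#' Assemble, validate, resolve and persist the configuration of a full
#' run. Recognized keys: `alpha1`, `alpha2`, `delta`, `theta_grid`,
#' `knowledge_draws`, `lambda2_grid_size`, `permutations`, `seed`.
#'
#' @param ... Key-value overrides.
#' @param file Optional YAML file of settings (overridden by `...`).
#' @return A named list of class `kddn_config` with all keys resolved.
#' @export
kddn_config <- function(..., file = NULL) {
  defaults <- list(alpha1 = 0.05, alpha2 = 0.05, delta = 0.1,
                   theta_grid = seq(0, 1, by = 0.1), knowledge_draws = 100,
                   lambda2_grid_size = 20, permutations = 50, seed = 1)
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file,
                                 call. = FALSE)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(cfg, over)
  }
  if (cfg$delta < 0 || cfg$delta >= 1) stop("delta must be in [0, 1)",
                                            call. = FALSE)
  structure(cfg, class = "kddn_config")
}

#' @export
print.kddn_config <- function(x, ...) {
  cat("<kddn_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(cfg)
}
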