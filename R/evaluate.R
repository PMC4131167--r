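# Labeled (pair, condition) item sets used by distance and scoring: a
# common edge contributes one item per condition.
labeled_items <- function(x) {
  # the second pass canonicalizes node order by name for plain edge tables
  et <- as_edge_table(as_edge_table(x))
  key <- function(cond) {
    sub <- et[et$condition %in% c(cond, "both"), , drop = FALSE]
    paste(sub$node_a, sub$node_b, sep = "\r")
  }
  list(cond1 = key("cond1"), cond2 = key("cond2"))
}

node_set <- function(x) {
  if (inherits(x, "kddn_fit")) return(x$genes)
  if (inherits(x, "kddn_truth")) return(x$genes)
  et <- as_edge_table(x)
  sort(unique(c(et$node_a, et$node_b)))
}

#' Graph edit distance between two condition-labeled network pairs
#'
#' Counts the edge insertions and deletions, per condition, needed to turn
#' one labeled network pair into the other:
#' \eqn{|E_A^{(1)} \Delta E_B^{(1)}| + |E_A^{(2)} \Delta E_B^{(2)}|}.
#' It is a metric on labeled edge sets.
#'
#' @param a,b `kddn_fit`, two-condition `kddn_truth`, or edge tables with
#'   `node_a`, `node_b`, `condition` columns. Node sets must agree when
#'   both are model objects.
#' @return Non-negative integer distance.
#' @examples
#' e1 <- tibble::tibble(node_a = c("g1", "g2"), node_b = c("g2", "g3"),
#'                      condition = "both")
#' e0 <- e1[0, ]
#' graph_edit_distance(e1, e0)  # 4: two edges in each of two conditions
#' @export
graph_edit_distance <- function(a, b) {
  na <- node_set(a)
  nb <- node_set(b)
  if ((inherits(a, "kddn_fit") || inherits(a, "kddn_truth")) &&
      (inherits(b, "kddn_fit") || inherits(b, "kddn_truth")) &&
      !setequal(na, nb)) {
    stop("node sets differ", call. = FALSE)
  }
  ia <- labeled_items(a)
  ib <- labeled_items(b)
  sym_diff <- function(u, v) length(setdiff(u, v)) + length(setdiff(v, u))
  sym_diff(ia$cond1, ib$cond1) + sym_diff(ia$cond2, ib$cond2)
}

#' Number of labeled edges in a network pair
#'
#' Counts (pair, condition) items, so a common edge contributes 2. This is
#' the `|E|` used in relative graph edit distances.
#'
#' @param x A `kddn_fit`, two-condition `kddn_truth`, or edge table.
#' @return Non-negative integer.
#' @export
n_labeled_edges <- function(x) {
  it <- labeled_items(x)
  length(it$cond1) + length(it$cond2)
}

#' Score an inferred network pair against the ground truth
#'
#' Precision, recall and F-score of the inferred labeled edges. The
#' `"overall"` scope counts (pair, condition) items, so a common edge
#' contributes two items and condition labels matter (`level = "pair"`
#' collapses to unlabeled pairs). The `"differential"` scope counts only
#' condition-exclusive edges, again as (pair, condition) items.
#'
#' @param est Estimated networks (`kddn_fit` or edge table).
#' @param truth A two-condition `kddn_truth` (or edge table).
#' @param scope `"overall"` or `"differential"`.
#' @param level `"condition"` (default) or `"pair"`.
#' @return A one-row tibble: `scope`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `fscore` (conventions: ratios are 0 when their denominator
#'   is 0).
#' @export
score_network <- function(est, truth, scope = c("overall", "differential"),
                          level = c("condition", "pair")) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  ne <- node_set(est)
  nt <- node_set(truth)
  if ((inherits(est, "kddn_fit") || inherits(est, "kddn_truth")) &&
      (inherits(truth, "kddn_fit") || inherits(truth, "kddn_truth")) &&
      !setequal(ne, nt)) {
    stop("node sets differ", call. = FALSE)
  }
  items <- function(x) {
    et <- as_edge_table(x)
    if (scope == "differential") et <- et[et$condition != "both", , drop = FALSE]
    if (level == "pair") {
      unique(paste(et$node_a, et$node_b, sep = "\r"))
    } else {
      it <- labeled_items(et)
      c(paste0("1\r", it$cond1, recycle0 = TRUE),
        paste0("2\r", it$cond2, recycle0 = TRUE))
    }
  }
  ie <- items(est)
  it <- items(truth)
  tp <- length(intersect(ie, it))
  fp <- length(setdiff(ie, it))
  fn <- length(setdiff(it, ie))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(scope = scope, tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, fscore = fscore)
}

#' Naive union baseline
#'
#' Superimposes the prior-knowledge network onto a data-only fit: every
#' knowledge edge is added to both conditions' edge sets (knowledge
#' carries no condition labels). The data-agnostic baseline the joint
#' model is compared against.
#'
#' @param data_only A `kddn_fit` obtained with `theta = 0` (or any fit).
#' @param knowledge A [kddn_prior].
#' @return An edge table (tibble with `node_a`, `node_b`, `condition`).
#' @export
naive_union_baseline <- function(data_only, knowledge) {
  stopifnot(inherits(knowledge, "kddn_prior"))
  et <- as_edge_table(data_only)
  W <- knowledge$W
  kp <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(kp) == 0L) return(et)
  genes <- knowledge$genes
  know <- tibble::tibble(node_a = genes[kp[, 1]], node_b = genes[kp[, 2]],
                         condition = "both")
  key <- paste(et$node_a, et$node_b, sep = "\r")
  kkey <- paste(know$node_a, know$node_b, sep = "\r")
  hit <- match(key, kkey)
  # edges named by knowledge become present in both conditions
  et$condition[!is.na(hit)] <- "both"
  dplyr::bind_rows(et, know[!(kkey %in% key), , drop = FALSE])
}

#' Robustness sweep over the knowledge false-positive rate
#'
#' Reproduces the shape of the simulation robustness study at configurable
#' scale: one GMRF truth pair and one data set are generated, the three
#' penalties are calibrated once on the data (`lambda1` by false-join
#' control, `lambda2` by permutation, `theta` against random knowledge
#' with `M` set to the number of common true edges), and then, for every
#' knowledge false-positive rate, `replicates` prior-knowledge sets are
#' drawn and the knowledge-fused fit, the data-only fit and the naive
#' union baseline are scored against the truth in both scopes.
#'
#' @param p Nodes.
#' @param n Samples per condition.
#' @param fp_rates False-positive rates to sweep.
#' @param replicates Knowledge draws per rate, at least 2.
#' @param delta Degradation budget for the theta calibration.
#' @param seed Integer seed; the sweep is deterministic given it.
#' @param rewire_fraction Fraction of rewired edges between conditions.
#' @param theta_draws Random-knowledge draws per theta grid value.
#' @param lambda2_splits Pseudo-splits for the fusion-penalty calibration.
#' @param alpha1,alpha2 Selection levels.
#'
#' @return A tibble with one row per scope x method x fp_rate:
#'   `mean`/`sd`/quartiles of precision and recall over replicates, plus
#'   the calibrated parameters as attributes (`"params"`, `"theta_hat"`)
#'   and the per-replicate scores in attribute `"replicates"`.
#' @export
run_fp_sweep <- function(p = 50, n = 150, fp_rates = c(0, 0.5, 1),
                         replicates = 50, delta = 0.1, seed = NULL,
                         rewire_fraction = 0.1, theta_draws = 100,
                         lambda2_splits = 50, alpha1 = 0.05, alpha2 = 0.05) {
  if (replicates < 2) stop("replicates must be at least 2", call. = FALSE)
  seeds <- with_seed_or_not(seed, sample.int(.Machine$integer.max, 4))
  truth <- perturb_network(simulate_gmrf_truth(p, seed = seeds[1]),
                           rewire_fraction, seed = seeds[1])
  data <- standardize(sample_condition_data(truth, n, seed = seeds[2]))
  lambda1 <- select_lambda1(data, alpha1)
  lambda2 <- select_lambda2(data, NULL, lambda1 = lambda1, theta = 0,
                            alpha2 = alpha2, B = lambda2_splits,
                            seed = seeds[3])
  m_common <- nrow(truth$E_common)
  cal <- select_theta(data, M = m_common,
                      params = kddn_params(lambda1 = lambda1,
                                           lambda2 = lambda2, delta = delta),
                      R = theta_draws, seed = seeds[3])
  theta_hat <- cal$theta_hat
  params0 <- kddn_params(lambda1 = lambda1, lambda2 = lambda2, theta = 0)
  fit0 <- kddn_fit(data, params = params0)
  score_both <- function(est) {
    dplyr::bind_rows(score_network(est, truth, "overall"),
                     score_network(est, truth, "differential"))
  }
  base0 <- score_both(fit0)

  rep_seeds <- matrix(
    with_seed_or_not(seeds[4],
      sample.int(.Machine$integer.max, length(fp_rates) * replicates)),
    nrow = replicates)
  per_rep <- purrr::map_dfr(seq_along(fp_rates), function(fi) {
    rate <- fp_rates[fi]
    purrr::map_dfr(seq_len(replicates), function(r) {
      pr <- make_prior_knowledge(truth, M = m_common, fp_rate = rate,
                                 seed = rep_seeds[r, fi])
      fitk <- kddn_fit(data, knowledge = pr,
                       params = kddn_params(lambda1 = lambda1,
                                            lambda2 = lambda2,
                                            theta = theta_hat))
      dplyr::bind_rows(
        dplyr::mutate(score_both(fitk), method = "kddn"),
        dplyr::mutate(score_both(naive_union_baseline(fit0, pr)),
                      method = "naive_union"),
        dplyr::mutate(base0, method = "data_only")
      ) |>
        dplyr::mutate(fp_rate = rate, replicate = r)
    })
  })

  summary <- per_rep |>
    tidyr::pivot_longer(c("precision", "recall"), names_to = "metric") |>
    dplyr::group_by(.data$scope, .data$method, .data$fp_rate, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      q1 = quantile(.data$value, 0.25), median = median(.data$value),
      q3 = quantile(.data$value, 0.75), .groups = "drop")
  attr(summary, "replicates") <- per_rep
  attr(summary, "params") <- list(lambda1 = lambda1, lambda2 = lambda2,
                                  theta_hat = theta_hat, delta = delta,
                                  M = m_common)
  attr(summary, "truth") <- truth
  summary
}
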