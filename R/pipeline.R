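#' Full knowledge-fused inference pipeline
#'
#' Calibrates all three penalties and fits the final model: `lambda1` by
#' false-join control, `lambda2` by permutation calibration of
#' differential-edge significance at `theta = 0`, then `theta` as the
#' largest knowledge weight whose worst-case (random-knowledge)
#' degradation stays within `delta` at the operating penalties, and
#' finally the knowledge-fused fit, optionally with permutation p-values
#' on the differential edges. Calibrating `theta` at the same `lambda2`
#' the final model uses keeps the degradation bound applicable to the
#' reported network; selecting `lambda2` at `theta = 0` keeps its null
#' calibration independent of the (unknown) prior quality.
#'
#' @param data A [kddn_data].
#' @param knowledge A [kddn_prior] or `NULL` (data-only inference).
#' @param config A [kddn_config] (or arguments to build one via `...`).
#' @param significance Compute permutation p-values for differential
#'   edges.
#' @param ... Config overrides passed to [kddn_config()].
#' @return A `kddn_fit` with the calibration attached as attributes
#'   `"theta_calibration"` and `"config"`.
#' @export
kddn <- function(data, knowledge = NULL, config = kddn_config(...),
                 significance = FALSE, ...) {
  data <- ensure_standardized(data)
  seeds <- with_seed_or_not(config$seed,
                            sample.int(.Machine$integer.max, 3))
  lambda1 <- select_lambda1(data, alpha1 = config$alpha1)
  lambda2 <- select_lambda2(data, knowledge = NULL, lambda1 = lambda1,
                            theta = 0, alpha2 = config$alpha2,
                            B = config$permutations,
                            n_grid = config$lambda2_grid_size,
                            seed = seeds[1])
  theta_hat <- 0
  cal <- NULL
  if (!is.null(knowledge)) {
    knowledge <- align_prior(knowledge, data$genes)
    cal <- select_theta(data, M = max(1L, knowledge$M),
                        params = kddn_params(lambda1 = lambda1,
                                             lambda2 = as.numeric(lambda2),
                                             delta = config$delta),
                        grid = config$theta_grid,
                        R = config$knowledge_draws, seed = seeds[2])
    theta_hat <- cal$theta_hat
  }
  fit <- kddn_fit(data, knowledge = knowledge,
                  params = kddn_params(lambda1 = lambda1,
                                       lambda2 = as.numeric(lambda2),
                                       theta = theta_hat,
                                       delta = config$delta,
                                       alpha1 = config$alpha1,
                                       alpha2 = config$alpha2))
  if (significance) {
    fit <- edge_significance(fit, knowledge = knowledge, B = 199,
                             seed = seeds[3])
  }
  attr(fit, "theta_calibration") <- cal
  attr(fit, "config") <- config
  fit
}
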