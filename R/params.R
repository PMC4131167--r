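#' Regularization and calibration parameters
#'
#' Container for the three regularization parameters of the joint model and
#' the levels governing their data-driven selection.
#'
#' @param lambda1 Sparsity penalty, >= 0 (or `NULL` to be selected by
#'   [select_lambda1()]).
#' @param lambda2 Fusion penalty on between-condition coefficient
#'   differences, >= 0 (or `NULL` to be selected by [select_lambda2()]).
#' @param theta Knowledge weight in `[0, 1]`; `theta = 0` ignores the prior
#'   entirely and must reproduce the data-only model exactly.
#' @param delta Acceptable worst-case degradation under random knowledge,
#'   in `[0, 1)`; used by [select_theta()].
#' @param alpha1 False-join level for the sparsity penalty.
#' @param alpha2 Differential-edge significance level for the fusion
#'   penalty.
#'
#' @return An object of class `kddn_params`.
#' @examples
#' kddn_params(lambda1 = 0.5, lambda2 = 0.05, theta = 0.3)
#' @export
kddn_params <- function(lambda1 = NULL, lambda2 = NULL, theta = 0,
                        delta = 0.1, alpha1 = 0.05, alpha2 = 0.05) {
  chk_range <- function(x, nm, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    if (is.null(x)) return(invisible())
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) stop("`", nm, "` out of range", call. = FALSE)
  }
  chk_range(lambda1, "lambda1", 0, Inf)
  chk_range(lambda2, "lambda2", 0, Inf)
  chk_range(theta, "theta", 0, 1)
  chk_range(delta, "delta", 0, 1, hi_open = TRUE)
  chk_range(alpha1, "alpha1", 0, 1, lo_open = TRUE, hi_open = TRUE)
  chk_range(alpha2, "alpha2", 0, 1, lo_open = TRUE, hi_open = TRUE)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, theta = theta,
         delta = delta, alpha1 = alpha1, alpha2 = alpha2),
    class = "kddn_params"
  )
}

#' @export
print.kddn_params <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<to select>" else format(v, digits = 4)
  cat("<kddn_params> lambda1 = ", fmt(x$lambda1),
      ", lambda2 = ", fmt(x$lambda2),
      ", theta = ", fmt(x$theta),
      ", delta = ", fmt(x$delta), "\n", sep = "")
  invisible(x)
}
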