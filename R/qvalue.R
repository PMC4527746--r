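#' Storey q-values
#'
#' Storey's false-discovery-rate estimator: the null proportion is
#' estimated as `pi0 = min(1, mean(p > lambda) / (1 - lambda))` at
#' `lambda = 0.5`, and each q-value is
#' `min over p_j >= p_i of pi0 * m * p_j / rank(p_j)` (ranks with ties
#' taking the maximum), capped at 1. Q-values are monotone non-decreasing
#' in p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning point for the null-proportion estimate.
#' @param pi0 Optional override of the estimated null proportion.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    .err("lohscan_input_error", "p-values must lie in [0, 1] with no NAs")
  .check_number(lambda, "lambda", 0, 1, lo_open = TRUE, hi_open = TRUE)
  m <- length(p)
  if (is.null(pi0)) pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  .check_number(pi0, "pi0", 0, 1)
  r <- rank(p, ties.method = "max")
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / r[o])
  pmin(q, 1)
}

#' Bonferroni per-test threshold
#'
#' Family-wise per-test significance threshold `alpha / n_tests`.
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Family-wise error level (default 0.05).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  n_tests <- .check_count(n_tests, "n_tests")
  .check_number(alpha, "alpha", 0, 1, lo_open = TRUE)
  alpha / n_tests
}
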