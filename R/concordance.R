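#' @importFrom stats cor.test
NULL

#' Cross-method concordance of per-variable estimates
#'
#' Ordinary least-squares regression of one estimate vector on another across
#' variables, with Pearson's correlation and its two-sided p -- the standard
#' way to summarise agreement between two analysis routes (e.g. Bayesian vs
#' multiple-imputation arm effects, or normal vs Poisson assumptions within
#' one method). An optional natural-log transform may be applied per axis
#' (positive values only).
#'
#' @param estimates_a,estimates_b Equal-length (>= 3) numeric vectors of
#'   per-variable estimates.
#' @param transform_a,transform_b `"identity"` or `"log"`.
#' @param labels Optional variable labels carried into the result.
#' @return Object of class `concordance`: a one-row tibble with `slope`,
#'   `intercept`, `r`, `r_squared`, `p_value`, `n`, `transform_a`,
#'   `transform_b`, and a `points` attribute (tibble of the plotted pairs).
#' @export
#' @examples
#' estimate_concordance(1:10, (1:10) * 2 + rnorm(10, 0, 0.1))
estimate_concordance <- function(estimates_a, estimates_b,
                                 transform_a = c("identity", "log"),
                                 transform_b = c("identity", "log"),
                                 labels = NULL) {
  transform_a <- match.arg(transform_a)
  transform_b <- match.arg(transform_b)
  ml_assert(length(estimates_a) == length(estimates_b),
            "estimate vectors must have equal length")
  ml_assert(length(estimates_a) >= 3, "need at least 3 points")
  ml_assert(all(is.finite(estimates_a)) && all(is.finite(estimates_b)),
            "estimates must be finite")
  tf <- function(x, t) {
    if (t == "log") {
      ml_assert(all(x > 0), "log transform requires positive values")
      log(x)
    } else x
  }
  a <- tf(estimates_a, transform_a)
  b <- tf(estimates_b, transform_b)
  if (var(a) == 0 || var(b) == 0) {
    rlang::warn("zero variance in an estimate vector; correlation undefined")
    out <- tibble::tibble(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          n = length(a), transform_a = transform_a,
                          transform_b = transform_b, degenerate = TRUE)
  } else {
    fit <- lm(b ~ a)
    ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
    out <- tibble::tibble(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value, n = length(a),
      transform_a = transform_a, transform_b = transform_b, degenerate = FALSE
    )
  }
  attr(out, "points") <- tibble::tibble(
    label = labels %||% as.character(seq_along(a)), a = a, b = b)
  class(out) <- c("concordance", class(out))
  out
}
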