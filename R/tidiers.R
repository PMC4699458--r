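#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an incomplete-MVN EM fit
#'
#' @param x An `mvn_em` object.
#' @param ... Unused.
#' @return A tibble with one row per variable: `variable`, `mean`,
#'   `variance`.
#' @export
tidy.mvn_em <- function(x, ...) {
  tibble::tibble(
    variable = x$variables %||% paste0("V", seq_len(x$p)),
    mean = x$mean, variance = diag(x$covariance))
}

#' @rdname tidy.mvn_em
#' @return `glance()`: a one-row tibble with `loglik`, `n_iter`, `converged`,
#'   `n`, `p`, `n_dropped`, `ridged`.
#' @export
glance.mvn_em <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n = x$n, p = x$p,
                 n_dropped = x$n_dropped, ridged = x$ridged)
}

#' Tidy Little's MCAR test
#'
#' @param x A `little_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic` (d2), `df`, `p_value`,
#'   `n_patterns`, `inapplicable`.
#' @export
tidy.little_test <- function(x, ...) {
  tibble::tibble(statistic = x$d2, df = x$df, p_value = x$p_value,
                 n_patterns = x$n_patterns, inapplicable = x$inapplicable)
}

#' Tidy a Bayesian data-augmentation fit
#'
#' @param x A `bayes_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the per-coefficient posterior summary tibble.
#' @export
tidy.bayes_fit <- function(x, ...) x$summary

#' @rdname tidy.bayes_fit
#' @return `glance()`: one row with `dic`, `dbar`, `pd`, `converged`,
#'   `acceptance`, `n_retained`, `n_chains`.
#' @export
glance.bayes_fit <- function(x, ...) {
  tibble::tibble(dic = x$dic$DIC, dbar = x$dic$Dbar, pd = x$dic$pD,
                 converged = x$converged, acceptance = x$acceptance,
                 n_retained = x$n_retained, n_chains = x$n_chains)
}

#' Tidy a Rubin-pooled estimate
#'
#' @param x A `pooled_estimate` object.
#' @param ... Unused.
#' @return The underlying tibble (term, estimate, variance components, df,
#'   statistic, p_value).
#' @export
tidy.pooled_estimate <- function(x, ...) tibble::as_tibble(x)
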