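#' @importFrom rlang %||% abort warn inform hash
#' @importFrom stats pnorm dnorm qnorm rnorm var sd cov complete.cases
NULL

# stop with a classed condition so tests can target specific failures
ml_abort <- function(msg, class) {
  rlang::abort(msg, class = paste0("misslong_", class))
}

ml_assert <- function(ok, msg, class = "validation") {
  if (!isTRUE(ok)) ml_abort(msg, class)
}

# local RNG scope: functions taking `seed` leave the global stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# symmetrize and, if needed, ridge a covariance matrix up to numerical PSD
psd_fix <- function(sigma, ridge = 1e-8) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge) {
    sigma <- sigma + diag(ridge - min(ev, 0), nrow(sigma))
    attr(sigma, "ridged") <- TRUE
  }
  sigma
}

# Moore-Penrose pseudo-inverse via SVD (used when an observed-block
# covariance is numerically singular)
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
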