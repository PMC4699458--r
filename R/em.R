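#' Maximum-likelihood estimation for incomplete multivariate normal data
#'
#' Fits the mean vector and covariance matrix of a multivariate normal by
#' expectation-maximisation over the observed-data likelihood. Rows are
#' grouped by missingness pattern; the E-step fills each pattern's missing
#' block with its conditional Gaussian moments given the observed block, and
#' the M-step updates the moments with denominator `n` (the MLE). The
#' observed-data log-likelihood is checked to be non-decreasing at every
#' iteration; convergence is declared when its successive change falls below
#' `tol`.
#'
#' @param data Numeric matrix or data frame (coerced) with `NA` for missing
#'   cells. Every column must be observed at least twice; rows with no
#'   observed cell are dropped with a warning.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations; non-convergence is flagged, never
#'   silently returned as converged.
#' @param start Optional starting values: a list with elements `mean` and
#'   `covariance`.
#' @param ridge Ridge added to keep a degenerate covariance numerically
#'   positive definite (flagged when used).
#' @param prior_df Weight (in pseudo-observations) of an inverse-Wishart-type
#'   shrinkage of the covariance toward its starting diagonal. The default 0
#'   is plain maximum likelihood with a strictly non-decreasing observed-data
#'   log-likelihood. A small positive value (a few percent of `n`) stabilises
#'   near-singular problems -- many variables, few rows, heavy missingness --
#'   where the unpenalised likelihood can degenerate; the penalised objective
#'   is then the monotone quantity.
#' @return An object of class `mvn_em`: a list with `mean`, `covariance`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n`, `p`, `n_dropped`,
#'   `ridged`, `prior_df`.
#' @export
#' @examples
#' x <- mvtnorm::rmvnorm(50, c(0, 0), diag(2))
#' x[1:10, 2] <- NA
#' fit <- em_fit(x)
#' fit$mean
em_fit <- function(data, tol = 1e-6, max_iter = 500L, start = NULL,
                   ridge = 1e-8, prior_df = 0) {
  y <- as.matrix(data)
  storage.mode(y) <- "double"
  p <- ncol(y)
  all_miss <- rowSums(!is.na(y)) == 0
  if (any(all_miss)) {
    rlang::warn(paste0(sum(all_miss), " all-missing row(s) dropped from EM"))
    y <- y[!all_miss, , drop = FALSE]
  }
  n <- nrow(y)
  obs_per_col <- colSums(!is.na(y))
  ml_assert(all(obs_per_col >= 2),
            "every column must be observed at least twice")

  # standardise columns internally (EM is affine-equivariant); the constant
  # relating the scaled to the raw log-likelihood is the log-Jacobian over
  # observed cells
  ctr <- colMeans(y, na.rm = TRUE)
  scl <- apply(y, 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  z <- sweep(sweep(y, 2, ctr), 2, scl, "/")
  ll_const <- -sum(log(scl)[col(y)[!is.na(y)]])

  if (is.null(start)) {
    mu <- colMeans(z, na.rm = TRUE)
    v <- apply(z, 2, var, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- ridge
    sigma <- diag(v, p)
    cc <- complete.cases(z)
    if (sum(cc) > p + 1) {
      s_cc <- cov(z[cc, , drop = FALSE]) * (sum(cc) - 1) / sum(cc)
      if (all(is.finite(s_cc))) sigma <- psd_fix(s_cc, ridge)
    }
  } else {
    mu <- (start$mean - ctr) / scl
    sigma <- psd_fix(t(start$covariance / scl) / scl, ridge)
  }
  s0 <- diag(pmax(diag(sigma), ridge), p) # shrinkage target (prior_df > 0)
  penalty <- function(sig) {
    if (prior_df <= 0) return(0)
    -(prior_df / 2) * (determinant(sig, logarithm = TRUE)$modulus[1] +
                         sum(diag(solve(sig, s0))))
  }

  pat_key <- apply(is.na(z), 1, function(m) paste(as.integer(m), collapse = ""))
  pats <- split(seq_len(n), pat_key)

  ridged <- isTRUE(attr(sigma, "ridged"))
  ll_trace <- numeric(0)
  obj_prev <- -Inf
  ll <- NA_real_
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    ll <- 0
    for (rows in pats) {
      o <- which(!is.na(z[rows[1], ]))
      m <- setdiff(seq_len(p), o)
      yo <- z[rows, o, drop = FALSE]
      k <- length(rows)
      s_oo <- sigma[o, o, drop = FALSE]
      ll <- ll + sum(mvtnorm::dmvnorm(yo, mu[o], s_oo, log = TRUE,
                                      checkSymmetry = FALSE))
      if (length(m) == 0) {
        t1 <- t1 + colSums(yo)
        t2[o, o] <- t2[o, o] + crossprod(yo)
        next
      }
      b <- tryCatch(t(solve(s_oo, t(sigma[m, o, drop = FALSE]))),
                    error = function(e)
                      sigma[m, o, drop = FALSE] %*% pseudo_inverse(s_oo))
      cen <- sweep(yo, 2, mu[o])
      em_mis <- matrix(mu[m], k, length(m), byrow = TRUE) + cen %*% t(b)
      cc_mis <- sigma[m, m, drop = FALSE] - b %*% sigma[o, m, drop = FALSE]
      t1[o] <- t1[o] + colSums(yo)
      t1[m] <- t1[m] + colSums(em_mis)
      t2[o, o] <- t2[o, o] + crossprod(yo)
      t2[o, m] <- t2[o, m] + crossprod(yo, em_mis)
      t2[m, o] <- t(t2[o, m, drop = FALSE])
      t2[m, m] <- t2[m, m] + crossprod(em_mis) + k * cc_mis
    }
    obj <- ll + penalty(sigma)
    # monotone guard: an EM (or penalised-EM) step can never decrease its
    # objective beyond numerical noise
    if (obj < obj_prev - 1e-6 * (1 + abs(obj_prev))) {
      ml_abort(sprintf(
        "EM objective decreased (%.8g -> %.8g)", obj_prev, obj),
        "em_monotonicity")
    }
    ll_trace <- c(ll_trace, ll + ll_const)
    if (is.finite(obj_prev) && abs(obj - obj_prev) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    mu <- t1 / n
    s_ml <- t2 / n - tcrossprod(mu)
    sigma_new <- if (prior_df > 0) {
      (n * s_ml + prior_df * s0) / (n + prior_df)
    } else s_ml
    sigma_new <- psd_fix(sigma_new, ridge)
    if (isTRUE(attr(sigma_new, "ridged"))) ridged <- TRUE
    sigma <- sigma_new
  }
  if (!converged) {
    rlang::warn(paste0("EM did not converge in ", max_iter, " iterations"))
  }

  sigma_raw <- t(sigma * scl) * scl
  structure(list(
    mean = as.numeric(mu * scl + ctr),
    covariance = unname(sigma_raw[seq_len(p), seq_len(p)]),
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    n_iter = iter, converged = converged, n = n, p = p,
    n_dropped = sum(all_miss), ridged = ridged, prior_df = prior_df,
    variables = colnames(y)
  ), class = "mvn_em")
}

#' @export
print.mvn_em <- function(x, ...) {
  cat("<mvn_em> p =", x$p, " n =", x$n,
      " loglik =", format(x$loglik, digits = 8),
      " iter =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Conditional Gaussian of the missing block given observed values
#'
#' Standard multivariate-normal conditioning: with observed indices `o` and
#' missing indices `m`, the conditional mean is
#' `mu_m + S_mo S_oo^{-1} (y_o - mu_o)` and the conditional covariance
#' `S_mm - S_mo S_oo^{-1} S_om`. A numerically singular observed block falls
#' back to the pseudo-inverse with a warning.
#'
#' @param params An `mvn_em` fit (or any list with `mean` and `covariance`).
#' @param observed_idx Integer indices of the observed variables (non-empty
#'   unless all variables are missing is desired; see Details).
#' @param observed_values Numeric vector of observed values, same length.
#' @return A list with `mean`, `cov` and `missing_idx` for the missing block;
#'   zero-dimensional when every variable is observed.
#' @export
conditional_dist <- function(params, observed_idx, observed_values) {
  mu <- params$mean
  sigma <- params$covariance
  p <- length(mu)
  ml_assert(length(observed_idx) >= 1 && all(observed_idx %in% seq_len(p)),
            "observed_idx must be a non-empty subset of 1..p")
  ml_assert(length(observed_values) == length(observed_idx),
            "observed_values must match observed_idx")
  o <- observed_idx
  m <- setdiff(seq_len(p), o)
  if (length(m) == 0) {
    return(list(mean = numeric(0), cov = matrix(0, 0, 0), missing_idx = integer(0)))
  }
  s_oo <- sigma[o, o, drop = FALSE]
  b <- tryCatch(t(solve(s_oo, t(sigma[m, o, drop = FALSE]))),
                error = function(e) {
                  rlang::warn("singular observed block; using pseudo-inverse")
                  sigma[m, o, drop = FALSE] %*% pseudo_inverse(s_oo)
                })
  cm <- mu[m] + as.numeric(b %*% (observed_values - mu[o]))
  cc <- sigma[m, m, drop = FALSE] - b %*% sigma[o, m, drop = FALSE]
  list(mean = cm, cov = psd_fix(cc), missing_idx = m)
}

#' Over-dispersed multi-start EM convergence check
#'
#' Re-runs [em_fit()] from `k_starts` perturbed starting points (means jittered
#' by one starting SD, covariance inflated by `inflation`) and reports whether
#' all runs land on the same optimum -- the dispersion diagnostic used to
#' confirm that EM found a global rather than local maximum.
#'
#' @param data As for [em_fit()].
#' @param k_starts Number of starts (>= 2).
#' @param inflation Covariance inflation factor for the starting values.
#' @param tol Agreement tolerance on final log-likelihoods (scaled) and
#'   parameter distance.
#' @param seed Integer seed for the perturbations.
#' @return A list with `runs` (tibble: start, loglik, n_iter, converged),
#'   `max_param_distance`, and `agree`.
#' @export
disperse_check <- function(data, k_starts = 5L, inflation = 2, tol = 1e-4,
                           seed = NULL) {
  ml_assert(is_scalar_number(k_starts) && k_starts >= 2,
            "k_starts must be >= 2")
  y <- as.matrix(data)
  p <- ncol(y)
  mu0 <- colMeans(y, na.rm = TRUE)
  v0 <- apply(y, 2, var, na.rm = TRUE)
  v0[!is.finite(v0) | v0 <= 0] <- 1e-8
  with_seed(seed, {
    fits <- purrr::map(seq_len(k_starts), function(i) {
      start <- list(mean = mu0 + rnorm(p, 0, sqrt(v0)),
                    covariance = diag(v0 * inflation, p))
      em_fit(y, start = start)
    })
    lls <- purrr::map_dbl(fits, "loglik")
    pars <- purrr::map(fits, ~ c(.x$mean, .x$covariance))
    dmax <- max(purrr::map_dbl(pars, function(a)
      max(purrr::map_dbl(pars, ~ max(abs(a - .x))))))
    scale <- max(1, max(abs(pars[[1]])))
    agree <- (max(lls) - min(lls)) < tol * (1 + abs(stats::median(lls))) &&
      dmax < tol * scale
    list(
      runs = tibble::tibble(start = seq_len(k_starts), loglik = lls,
                            n_iter = purrr::map_int(fits, "n_iter"),
                            converged = purrr::map_lgl(fits, "converged")),
      max_param_distance = dmax,
      agree = agree
    )
  })
}
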