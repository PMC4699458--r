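#' @importFrom stats model.matrix rpois dpois acf setNames lm.fit glm.fit
#'   median
NULL

#' One-step full-Bayesian GLM with response augmentation
#'
#' Fits `response ~ covariates` by MCMC in which the missing responses are
#' sampled jointly with the parameters (data augmentation), so imputation and
#' analysis happen in a single model rather than as separate steps.
#'
#' Normal likelihood: a Gibbs sampler with conjugate updates -- coefficients
#' from their multivariate-normal full conditional, the residual variance
#' from an inverse-gamma (weak prior, shape 0.001, rate 0.001), and each
#' missing response from `N(x'beta, sigma^2)` every sweep. Poisson
#' likelihood: the response is rounded to a count on its natural (percent)
#' scale, coefficients move by adaptive random-walk Metropolis (scale tuned
#' during burn-in towards ~30% acceptance), and missing responses are drawn
#' from `Poisson(exp(x'beta))`.
#'
#' Priors are weakly informative and data-derived: each coefficient gets a
#' normal prior centred at 0 with scale `prior_scale_mult` times the SD of
#' the observed response.
#'
#' Chains (>= 2 by default, so the Gelman-Rubin statistic is always
#' computable) start from over-dispersed points; the first `burn_in` draws of
#' each chain are discarded. A coefficient R-hat above 1.1 flags the fit as
#' non-converged; a Metropolis acceptance rate outside [0.05, 0.8] after
#' adaptation warns.
#'
#' @param data Data frame; the response may contain `NA` (augmented), the
#'   covariates must be fully observed.
#' @param response Response column name (>= 10 observed values).
#' @param covariates Character vector of covariate columns; `character(0)`
#'   fits an intercept-only model.
#' @param likelihood `"normal"` or `"poisson"`.
#' @param n_iter Total MCMC sweeps per chain (default 100000; any smaller
#'   value such as 50000 or 10000 is supported).
#' @param burn_in Discarded initial sweeps per chain (default 4000).
#' @param n_chains Number of chains (>= 2 recommended).
#' @param thin Thinning interval.
#' @param seed Integer seed.
#' @param prior_scale_mult Prior SD multiplier on the observed-response SD.
#' @param prior_sd Optional explicit coefficient prior SD (scalar or length-k
#'   vector), overriding the data-derived scale.
#' @param sigma2_fixed Optional known residual variance (normal mode): the
#'   variance update is skipped and the model becomes the conjugate
#'   normal-normal case.
#' @param proposal_scale Optional initial Metropolis scale (Poisson mode).
#' @param keep_imputations Retain posterior draws of the augmented cells.
#' @return Object of class `bayes_fit`: list with `summary` (tibble: term,
#'   mean, sd, q2.5, q97.5, rhat, ess, p_value), `dic` (list DIC/Dbar/pD),
#'   `likelihood`, `converged`, `acceptance`, `n_retained`, `draws` (list of
#'   per-chain coefficient matrices), optional `imputation_draws`.
#' @export
#' @examples
#' d <- data.frame(arm = rep(0:1, each = 20))
#' d$y <- 5 + 2 * d$arm + rnorm(40)
#' d$y[1:8] <- NA
#' fit <- fit_bayes(d, "y", "arm", n_iter = 2000, burn_in = 500, seed = 1)
#' fit$summary
fit_bayes <- function(data, response, covariates = "arm",
                      likelihood = c("normal", "poisson"),
                      n_iter = 100000L, burn_in = 4000L, n_chains = 2L,
                      thin = 1L, seed = NULL, prior_scale_mult = 10,
                      prior_sd = NULL, sigma2_fixed = NULL,
                      proposal_scale = NULL, keep_imputations = FALSE) {
  likelihood <- match.arg(likelihood)
  ml_assert(burn_in < n_iter, "burn_in must be smaller than n_iter")
  ml_assert(n_chains >= 1, "need at least one chain")
  y <- data[[response]]
  # the >= 10 observation floor guards the residual-variance estimation;
  # with a known variance the conjugate model is proper from 2 observations
  min_obs <- if (!is.null(sigma2_fixed)) 2L else 10L
  ml_assert(sum(!is.na(y)) >= min_obs,
            "response needs at least 10 observed values")
  x <- if (length(covariates) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    ml_assert(!anyNA(data[covariates]), "covariates must be fully observed")
    model.matrix(reformulate(covariates), data = data)
  }
  k <- ncol(x)
  obs <- which(!is.na(y))
  mis <- which(is.na(y))

  if (likelihood == "poisson") {
    yc <- y
    yc[obs] <- round(y[obs]) # counts on the natural (percent) scale
    ml_assert(all(yc[obs] >= 0), "Poisson mode needs a non-negative response")
    y <- yc
  }
  # data-derived prior scale on the scale the coefficients live on:
  # response SD under the identity link, SD of the log response under log
  sd_y <- if (likelihood == "normal") sd(y[obs]) else sd(log1p(y[obs]))
  if (!is.finite(sd_y) || sd_y <= 0) sd_y <- 1
  prior_sd <- rep(prior_sd %||% (prior_scale_mult * sd_y), length.out = k)

  retain_idx <- seq(burn_in + 1L, n_iter, by = thin)
  with_seed(seed, {
    chains <- vector("list", n_chains)
    dev_chains <- vector("list", n_chains)
    sig_chains <- vector("list", n_chains)
    imp_chains <- if (keep_imputations) vector("list", n_chains)
    acc_rates <- numeric(n_chains)
    # over-dispersed starts around a crude complete-case estimate
    beta0 <- tryCatch({
      if (likelihood == "normal") {
        coef(lm.fit(x[obs, , drop = FALSE], y[obs]))
      } else {
        coef(suppressWarnings(glm.fit(x[obs, , drop = FALSE], y[obs],
                                      family = quasipoisson(link = "log"))))
      }
    }, error = function(e) numeric(k))
    beta0[!is.finite(beta0)] <- 0
    # over-dispersion of the starting points, on the coefficient scale
    start_sd <- if (likelihood == "normal") sd(y[obs]) else 0.5
    for (ch in seq_len(n_chains)) {
      disp <- (2 * (ch - 1) / max(n_chains - 1, 1) - 1) * 2 # in [-2, 2]
      start <- beta0 + disp * start_sd
      res <- if (likelihood == "normal") {
        gibbs_normal(y, x, obs, mis, start, prior_sd, n_iter, retain_idx,
                     keep_imputations, sigma2_fixed)
      } else {
        metropolis_poisson(y, x, obs, mis, start, prior_sd, n_iter, burn_in,
                           retain_idx, proposal_scale, keep_imputations)
      }
      chains[[ch]] <- res$beta
      dev_chains[[ch]] <- res$deviance
      sig_chains[[ch]] <- res$sigma2
      acc_rates[ch] <- res$acceptance
      if (keep_imputations) imp_chains[[ch]] <- res$imputed
    }

    all_beta <- do.call(rbind, chains)
    summ <- purrr::map_dfr(seq_len(k), function(j) {
      per_chain <- purrr::map(chains, ~ .x[, j])
      draws <- unlist(per_chain)
      rh <- if (n_chains >= 2) gelman_rubin(per_chain) else NA_real_
      tibble::tibble(
        term = colnames(x)[j], mean = mean(draws), sd = sd(draws),
        q2.5 = quantile(draws, 0.025), q97.5 = quantile(draws, 0.975),
        rhat = rh, ess = sum(purrr::map_dbl(per_chain, ess_one)),
        p_value = 2 * pnorm(-abs(mean(draws) / sd(draws)))
      )
    })

    # DIC from the observed-data deviance draws and the deviance at the
    # posterior parameter means
    beta_bar <- colMeans(all_beta)
    dev_at_mean <- if (likelihood == "normal") {
      s2_bar <- mean(unlist(sig_chains))
      -2 * sum(dnorm(y[obs], as.numeric(x[obs, , drop = FALSE] %*% beta_bar),
                     sqrt(s2_bar), log = TRUE))
    } else {
      -2 * sum(dpois(y[obs], exp(as.numeric(x[obs, , drop = FALSE] %*% beta_bar)),
                     log = TRUE))
    }
    dic_res <- dic(unlist(dev_chains), dev_at_mean)

    acc <- if (likelihood == "poisson") mean(acc_rates) else NA_real_
    if (likelihood == "poisson" && (acc < 0.05 || acc > 0.8)) {
      rlang::warn(sprintf("Metropolis acceptance %.2f outside [0.05, 0.8]", acc))
    }
    converged <- !(n_chains >= 2 && any(summ$rhat > 1.1, na.rm = TRUE))

    structure(list(
      summary = summ, dic = dic_res, likelihood = likelihood,
      converged = converged, acceptance = acc,
      n_retained = length(retain_idx), n_chains = n_chains,
      burn_in = burn_in, thin = thin, draws = chains,
      imputation_draws = if (keep_imputations) imp_chains,
      response = response, n_missing = length(mis)
    ), class = "bayes_fit")
  })
}

gibbs_normal <- function(y, x, obs, mis, beta, prior_sd, n_iter, retain_idx,
                         keep_imputations, sigma2_fixed = NULL) {
  k <- ncol(x)
  n <- nrow(x)
  a0 <- 0.001; b0 <- 0.001
  prior_prec <- diag(1 / prior_sd^2, k)
  xtx <- crossprod(x)
  x_mis <- x[mis, , drop = FALSE]
  yy <- y
  r0 <- y[obs] - as.numeric(x[obs, , drop = FALSE] %*% beta)
  sigma2 <- sigma2_fixed %||% max(var(r0), 1e-6)
  out_beta <- matrix(NA_real_, length(retain_idx), k,
                     dimnames = list(NULL, colnames(x)))
  out_dev <- numeric(length(retain_idx))
  out_sig <- numeric(length(retain_idx))
  out_imp <- if (keep_imputations && length(mis))
    matrix(NA_real_, length(retain_idx), length(mis))
  keep <- logical(n_iter); keep[retain_idx] <- TRUE
  pos <- 0L
  for (it in seq_len(n_iter)) {
    if (length(mis)) {
      yy[mis] <- as.numeric(x_mis %*% beta) + rnorm(length(mis), 0, sqrt(sigma2))
    }
    prec <- xtx / sigma2 + prior_prec
    ch <- chol(prec)
    bmean <- backsolve(ch, forwardsolve(t(ch), crossprod(x, yy) / sigma2))
    beta <- as.numeric(bmean + backsolve(ch, rnorm(k)))
    if (is.null(sigma2_fixed)) {
      resid <- yy - as.numeric(x %*% beta)
      sigma2 <- 1 / rgamma(1, a0 + n / 2, b0 + sum(resid^2) / 2)
    }
    if (keep[it]) {
      pos <- pos + 1L
      out_beta[pos, ] <- beta
      out_sig[pos] <- sigma2
      out_dev[pos] <- -2 * sum(dnorm(y[obs],
        as.numeric(x[obs, , drop = FALSE] %*% beta), sqrt(sigma2), log = TRUE))
      if (!is.null(out_imp)) out_imp[pos, ] <- yy[mis]
    }
  }
  list(beta = out_beta, deviance = out_dev, sigma2 = out_sig,
       acceptance = NA_real_, imputed = out_imp)
}

metropolis_poisson <- function(y, x, obs, mis, beta, prior_sd, n_iter, burn_in,
                               retain_idx, proposal_scale, keep_imputations) {
  k <- ncol(x)
  x_obs <- x[obs, , drop = FALSE]
  x_mis <- x[mis, , drop = FALSE]
  yy <- y
  if (length(mis)) yy[mis] <- round(mean(y[obs]))
  logpost <- function(beta, yfull) {
    eta <- as.numeric(x %*% beta)
    if (max(eta) > 30) return(-Inf)
    sum(yfull * eta - exp(eta)) - sum(beta^2 / (2 * prior_sd^2))
  }
  scale <- proposal_scale %||% 0.1
  # proposal shape from a crude quasi-likelihood curvature estimate
  prop_chol <- tryCatch({
    w <- pmax(exp(as.numeric(x_obs %*% beta)), 1e-3)
    h <- crossprod(x_obs * w, x_obs) + diag(1 / prior_sd^2, k)
    chol(solve(h))
  }, error = function(e) diag(1, k))
  lp <- logpost(beta, yy)
  out_beta <- matrix(NA_real_, length(retain_idx), k,
                     dimnames = list(NULL, colnames(x)))
  out_dev <- numeric(length(retain_idx))
  out_imp <- if (keep_imputations && length(mis))
    matrix(NA_real_, length(retain_idx), length(mis))
  keep <- logical(n_iter); keep[retain_idx] <- TRUE
  pos <- 0L
  acc_post <- 0L; n_post <- 0L
  for (it in seq_len(n_iter)) {
    if (length(mis)) {
      lam <- exp(pmin(as.numeric(x_mis %*% beta), 30))
      yy[mis] <- rpois(length(mis), lam)
      lp <- logpost(beta, yy)
    }
    prop <- beta + scale * as.numeric(crossprod(prop_chol, rnorm(k)))
    lp_prop <- logpost(prop, yy)
    accepted <- log(runif(1)) < lp_prop - lp
    if (accepted) { beta <- prop; lp <- lp_prop }
    if (it <= burn_in) {
      # Robbins-Monro adaptation towards 30% acceptance
      scale <- exp(log(scale) + (as.numeric(accepted) - 0.3) / max(it^0.6, 1))
    } else {
      n_post <- n_post + 1L
      acc_post <- acc_post + as.numeric(accepted)
    }
    if (keep[it]) {
      pos <- pos + 1L
      out_beta[pos, ] <- beta
      out_dev[pos] <- -2 * sum(dpois(y[obs],
        exp(pmin(as.numeric(x_obs %*% beta), 30)), log = TRUE))
      if (!is.null(out_imp)) out_imp[pos, ] <- yy[mis]
    }
  }
  list(beta = out_beta, deviance = out_dev, sigma2 = NULL,
       acceptance = if (n_post > 0) acc_post / n_post else NA_real_,
       imputed = out_imp)
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit>", x$likelihood, "likelihood,", x$n_chains, "chains x",
      x$n_retained, "retained draws",
      if (!x$converged) "[NOT converged]" else "", "\n")
  print(x$summary)
  cat(sprintf("DIC %.2f (Dbar %.2f, pD %.2f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variability of a scalar quantity:
#' with within-chain variance `W` (mean of the per-chain variances) and
#' between-chain variance of the chain means `B/n`, returns
#' `sqrt((W + B/n) / W)`. The statistic is 1 exactly when the chains are
#' indistinguishable and grows as the chains separate; values near 1
#' indicate convergence.
#'
#' @param chains List (or matrix columns) of >= 2 equal-length (>= 10) draw
#'   vectors of one scalar.
#' @return The R-hat value; `NA` with a warning if the within-chain variance
#'   is zero.
#' @export
#' @examples
#' z <- rnorm(1000)
#' gelman_rubin(list(z, z)) # identical chains: exactly 1
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  ml_assert(length(chains) >= 2, "need at least two chains")
  len <- lengths(chains)
  ml_assert(length(unique(len)) == 1 && len[1] >= 10,
            "chains must have equal length >= 10")
  w <- mean(purrr::map_dbl(chains, var))
  if (w <= 0) {
    rlang::warn("zero within-chain variance; R-hat undefined")
    return(NA_real_)
  }
  b_over_n <- var(purrr::map_dbl(chains, mean))
  sqrt((w + b_over_n) / w)
}

# effective sample size of one chain: initial positive-sequence estimator
# on the autocorrelation function
ess_one <- function(draws) {
  n <- length(draws)
  if (var(draws) <= 0) return(n)
  rho <- as.numeric(acf(draws, lag.max = min(n - 1, 200), plot = FALSE,
                        demean = TRUE)$acf)[-1]
  s <- 0
  for (i in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[i] + rho[i + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance, `pD = Dbar - D(theta_bar)` the
#' effective number of parameters, and `DIC = Dbar + pD`. Lower DIC is
#' preferred in model selection.
#'
#' @param deviance_draws Numeric vector of deviance draws (>= 2).
#' @param deviance_at_posterior_mean Deviance evaluated at the posterior
#'   parameter means.
#' @return List with `DIC`, `Dbar`, `pD`.
#' @export
dic <- function(deviance_draws, deviance_at_posterior_mean) {
  ml_assert(length(deviance_draws) >= 2, "need at least two deviance draws")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_posterior_mean
  list(DIC = dbar + pd, Dbar = dbar, pD = pd)
}
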