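test_that("R-hat is exactly 1 for identical chains and grows with separation", {
  z <- withr::with_seed(1, rnorm(1000))
  expect_identical(gelman_rubin(list(z, z)), 1)

  withr::with_seed(2, {
    a <- rnorm(10000)
    b <- rnorm(10000)
    expect_lt(gelman_rubin(list(a, b)), 1.01)
    expect_gt(gelman_rubin(list(a, b + 10)), 1.1)
  })

  expect_warning(rh <- gelman_rubin(list(rep(1, 20), rep(1, 20))),
                 "undefined")
  expect_true(is.na(rh))
  expect_error(gelman_rubin(list(rnorm(20))), "two chains")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "length")
})

test_that("R-hat agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  withr::with_seed(3, {
    a <- as.numeric(arima.sim(list(ar = 0.6), 5000))
    b <- as.numeric(arima.sim(list(ar = 0.6), 5000))
    ours <- gelman_rubin(list(a, b))
    ref <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(a), coda::mcmc(b)),
                             autoburnin = FALSE)$psrf[1]
    expect_equal(ours, ref, tolerance = 0.01)
  })
})

test_that("DIC components follow their definitions", {
  out <- dic(rep(12.5, 50), 12.5)
  expect_equal(out$pD, 0)
  expect_equal(out$DIC, out$Dbar)
  expect_equal(out$Dbar, 12.5)

  out2 <- dic(c(10, 14), 9)
  expect_equal(out2$Dbar, 12)
  expect_equal(out2$pD, 3)
  expect_equal(out2$DIC, 15)
  expect_error(dic(5, 5), "two deviance draws")
})

test_that("known-variance toy matches the conjugate closed form", {
  yv <- withr::with_seed(4, rnorm(4, 2, 1))
  d <- data.frame(y = yv)
  fit <- fit_bayes(d, "y", character(0), n_iter = 20000, burn_in = 2000,
                   seed = 5, prior_sd = 1, sigma2_fixed = 1)
  post_var <- 1 / (1 + 4)
  post_mean <- post_var * sum(yv)
  mc_se <- fit$summary$sd / sqrt(fit$summary$ess)
  expect_lt(abs(fit$summary$mean - post_mean), 4 * mc_se)
  expect_lt(abs(fit$summary$sd^2 - post_var) / post_var, 0.05)
})

test_that("near-flat priors recover the OLS fit", {
  withr::with_seed(6, {
    d <- data.frame(arm = rep(0:1, each = 100))
    d$y <- 2 + 1.5 * d$arm + rnorm(200)
    fit <- fit_bayes(d, "y", "arm", n_iter = 8000, burn_in = 2000, seed = 7,
                     prior_scale_mult = 1e4)
    ols <- summary(lm(y ~ arm, d))$coefficients
    arm <- fit$summary[fit$summary$term == "arm", ]
    mc_se <- arm$sd / sqrt(arm$ess)
    expect_lt(abs(arm$mean - ols["arm", 1]), 2 * pmax(mc_se, 0.005))
    expect_lt(abs(arm$sd - ols["arm", 2]) / ols["arm", 2], 0.1)
    expect_true(fit$converged)
  })
})

test_that("an intercept-only model tracks the observed mean", {
  withr::with_seed(8, {
    d <- data.frame(y = rnorm(60, 7, 2))
    fit <- fit_bayes(d, "y", character(0), n_iter = 4000, burn_in = 1000,
                     seed = 9)
    expect_lt(abs(fit$summary$mean - mean(d$y)), 0.1)
  })
})

test_that("missing responses are augmented, not dropped", {
  withr::with_seed(10, {
    d <- data.frame(arm = rep(0:1, each = 40))
    d$y <- 20 + 5 * d$arm + rnorm(80, 0, 4)
    d$y[sample(80, 24)] <- NA
    fit <- fit_bayes(d, "y", "arm", n_iter = 6000, burn_in = 1000, seed = 11,
                     keep_imputations = TRUE)
    arm <- fit$summary[fit$summary$term == "arm", ]
    expect_lt(abs(arm$mean - 5), 4 * arm$sd)
    expect_equal(fit$n_missing, 24L)
    expect_equal(dim(fit$imputation_draws[[1]]), c(5000L, 24L))
  })
})

test_that("retained draw counts follow n_iter, burn_in and thin", {
  d <- data.frame(y = rnorm(30))
  fit <- fit_bayes(d, "y", character(0), n_iter = 3000, burn_in = 1000,
                   thin = 4, seed = 12)
  expect_equal(fit$n_retained, 500L)
  expect_equal(nrow(fit$draws[[1]]), 500L)
  expect_equal(fit$burn_in, 1000L)
  expect_error(fit_bayes(d, "y", character(0), n_iter = 100, burn_in = 200),
               "burn_in")
})

test_that("Poisson mode targets the log mean ratio with sane acceptance", {
  withr::with_seed(13, {
    d <- data.frame(arm = rep(0:1, each = 60))
    d$y <- rpois(120, exp(3.5 + 0.2 * d$arm))
    fit <- fit_bayes(d, "y", "arm", likelihood = "poisson", n_iter = 8000,
                     burn_in = 3000, seed = 14)
    arm <- fit$summary[fit$summary$term == "arm", ]
    expect_lt(abs(arm$mean - 0.2), 4 * arm$sd)
    expect_gt(fit$acceptance, 0.05)
    expect_lt(fit$acceptance, 0.8)
    expect_true(fit$converged)
    # effective parameter count near the sampled dimension
    expect_lt(abs(fit$dic$pD - 2) / 2, 0.5)
  })
})

test_that("fit summaries are exposed through broom-style generics", {
  d <- data.frame(y = rnorm(40, 5))
  fit <- fit_bayes(d, "y", character(0), n_iter = 2000, burn_in = 500,
                   seed = 15)
  expect_identical(generics::tidy(fit), fit$summary)
  gl <- generics::glance(fit)
  expect_named(gl, c("dic", "dbar", "pd", "converged", "acceptance",
                     "n_retained", "n_chains"))
})
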