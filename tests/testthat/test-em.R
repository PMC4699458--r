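test_that("complete data recovers the closed-form MLE", {
  set.seed(1)
  x <- mvtnorm::rmvnorm(40, c(1, -2, 0.5), diag(3) + 0.4)
  fit <- em_fit(x, tol = 1e-10)
  expect_equal(fit$mean, colMeans(x), tolerance = 1e-8)
  expect_equal(fit$covariance, cov(x) * 39 / 40, tolerance = 1e-7)
  expect_true(fit$converged)
})

test_that("EM matches direct likelihood maximisation on tiny instances", {
  cases <- list(
    withr::with_seed(2, {
      x <- mvtnorm::rmvnorm(6, c(0, 0), matrix(c(1, .6, .6, 1), 2))
      x[1, 2] <- NA
      x
    }),
    withr::with_seed(3, {
      x <- mvtnorm::rmvnorm(8, c(1, 0, -1), diag(3) + 0.3)
      x[1, 1] <- NA; x[2, 3] <- NA; x[5, 2:3] <- NA
      x
    }),
    withr::with_seed(4, {
      x <- mvtnorm::rmvnorm(7, c(0, 0), diag(2))
      x[c(1, 4), 1] <- NA
      x
    })
  )
  for (x in cases) {
    fit <- em_fit(x, tol = 1e-12, max_iter = 5000)
    oracle <- direct_mvn_mle(x)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-5)
  }
})

test_that("observed-data log-likelihood never decreases", {
  for (s in 1:5) {
    x <- mcar_bivariate(60, rho = 0.7, miss = 0.35, seed = s)
    fit <- em_fit(x, tol = 1e-9)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 *
                      (1 + abs(fit$loglik_trace[-length(fit$loglik_trace)]))))
  }
})

test_that("MCAR estimates are consistent at moderate n", {
  withr::with_seed(9, {
    sigma <- matrix(c(2, 0.8, 0.8, 1), 2)
    x <- mvtnorm::rmvnorm(2000, c(3, -1), sigma)
    x[runif(2000) < 0.3, 2] <- NA
    fit <- em_fit(x)
    # 3 Monte-Carlo standard errors of the generating parameters
    expect_lt(abs(fit$mean[1] - 3), 3 * sqrt(2 / 2000))
    expect_lt(abs(fit$mean[2] + 1), 3 * sqrt(1 / (2000 * 0.7)))
    expect_lt(abs(fit$covariance[1, 2] - 0.8), 0.15)
  })
})

test_that("degenerate and pathological inputs are handled explicitly", {
  x <- cbind(rnorm(10), rep(5, 10))
  x[1, 1] <- NA
  fit <- suppressWarnings(em_fit(x))
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$covariance)))

  y <- mcar_bivariate(20, 0.5, 0.3, seed = 6)
  y <- rbind(y, c(NA, NA))
  expect_warning(fit2 <- em_fit(y), "all-missing")
  expect_equal(fit2$n_dropped, 1L)
  expect_equal(fit2$n, 20L)

  z <- cbind(rnorm(10), c(1.2, rep(NA, 9)))
  expect_error(em_fit(z), "observed at least twice")

  expect_warning(em_fit(mcar_bivariate(60, .7, .4, seed = 7), max_iter = 2L),
                 "did not converge")
})

test_that("non-convergence is flagged, never silently returned", {
  fit <- suppressWarnings(em_fit(mcar_bivariate(60, .7, .4, seed = 7),
                                 max_iter = 2L))
  expect_false(fit$converged)
})

test_that("Gaussian conditioning matches the closed form", {
  params <- list(mean = c(0, 0), covariance = matrix(c(1, .5, .5, 1), 2))
  cd <- conditional_dist(params, observed_idx = 1, observed_values = 2)
  expect_equal(cd$mean, 1.0)
  expect_equal(cd$cov[1, 1], 0.75)

  # independence: conditional equals marginal
  ind <- list(mean = c(2, 5), covariance = diag(c(1, 4)))
  cd2 <- conditional_dist(ind, 1, 0)
  expect_equal(cd2$mean, 5)
  expect_equal(cd2$cov[1, 1], 4)

  # everything observed: zero-dimensional conditional
  cd3 <- conditional_dist(params, 1:2, c(0.3, -0.2))
  expect_length(cd3$mean, 0)
  expect_equal(dim(cd3$cov), c(0L, 0L))

  expect_error(conditional_dist(params, integer(0), numeric(0)),
               "non-empty")

  # singular observed block falls back to the pseudo-inverse with a warning
  sing <- list(mean = c(0, 0, 0),
               covariance = matrix(c(1, 1, .5, 1, 1, .5, .5, .5, 1), 3))
  expect_warning(cd4 <- conditional_dist(sing, 1:2, c(1, 1)), "singular")
  expect_true(all(is.finite(cd4$mean)))
})

test_that("over-dispersed starts agree on the optimum", {
  x <- withr::with_seed(11, {
    x <- mvtnorm::rmvnorm(200, numeric(5), diag(5) + 0.3)
    x[runif(200) < 0.3, 4:5] <- NA
    x
  })
  chk <- disperse_check(x, k_starts = 5, seed = 12)
  expect_true(chk$agree)
  expect_true(all(chk$runs$converged))

  cmp <- disperse_check(mvtnorm::rmvnorm(50, c(0, 0), diag(2)),
                        k_starts = 3, seed = 13)
  expect_true(cmp$agree)

  expect_error(disperse_check(x, k_starts = 1), ">= 2")
})

test_that("tidiers expose the fit as tibbles", {
  fit <- em_fit(mcar_bivariate(50, 0.4, 0.2, seed = 14))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("variable", "mean", "variance"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 50L)
})
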