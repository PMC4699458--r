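test_that("welch_t behaves at its boundary cases", {
  same <- welch_t(10, 2, 30, 10, 2, 30)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # vectorised over rows, p shrinks as the separation grows
  out <- welch_t(c(10, 12, 14), 2, 20, 10, 2, 20)
  expect_equal(nrow(out), 3)
  expect_true(all(diff(out$p_value) < 0))

  # agrees with t.test on raw data
  withr::with_seed(1, {
    a <- rnorm(23, 42.5, 6.8)
    b <- rnorm(66, 36.0, 8.5)
    ours <- welch_t(mean(a), sd(a), 23, mean(b), sd(b), 66)
    ref <- t.test(a, b)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  })

  expect_error(welch_t(1, 1, 1, 2, 1, 5), ">= 2")
  expect_error(welch_t(1, 0, 5, 2, 1, 5), "> 0")
})

test_that("bonferroni flags follow the family-size threshold", {
  expect_false(any(bonferroni(rep(1, 10))))
  expect_identical(bonferroni(0.04, m = 1), TRUE)  # M = 1: unadjusted
  expect_identical(bonferroni(c(0.004, 0.006), m = 10), c(TRUE, FALSE))
  expect_error(bonferroni(numeric(0)), "empty")
})

test_that("normal-identity arm coefficient equals the mean difference", {
  withr::with_seed(2, {
    d <- tibble::tibble(arm = rep(0:1, c(14, 19)),
                        y = rnorm(33, 30 + 4 * rep(0:1, c(14, 19)), 6))
    fit <- glm_fit(d, "y", family = "normal", covariates = "arm")
    diff <- mean(d$y[d$arm == 1]) - mean(d$y[d$arm == 0])
    expect_equal(fit$estimate[fit$term == "arm"], diff, tolerance = 1e-12)
  })
})

test_that("poisson-log arm coefficient is the log ratio of group means", {
  withr::with_seed(3, {
    d <- tibble::tibble(arm = rep(0:1, each = 25),
                        y = abs(rnorm(50, 38 + 4 * rep(0:1, each = 25), 7)))
    fit <- glm_fit(d, "y", family = "poisson", covariates = "arm")
    lr <- log(mean(d$y[d$arm == 1]) / mean(d$y[d$arm == 0]))
    expect_equal(fit$estimate[fit$term == "arm"], lr, tolerance = 1e-8)

    # the literal log(100 * proportion) coding models the logged response
    fl <- glm_fit(d, "y", family = "poisson", covariates = "arm",
                  coding = "log100")
    lr_log <- log(mean(log(d$y[d$arm == 1])) / mean(log(d$y[d$arm == 0])))
    expect_equal(fl$estimate[fl$term == "arm"], lr_log, tolerance = 1e-8)
  })

  neg <- tibble::tibble(arm = rep(0:1, each = 5), y = c(-1, rnorm(9, 5)))
  expect_error(glm_fit(neg, "y", family = "poisson", covariates = "arm"),
               class = "misslong_nonpositive")
  expect_warning(glm_fit(neg, "y", family = "poisson", covariates = "arm",
                         on_nonpositive = "shift"), "shift")
})

test_that("Rubin pooling follows the combining formulas", {
  fits <- purrr::map(c(1.0, 1.2, 0.8, 1.1, 0.9), function(q)
    structure(tibble::tibble(term = "arm", estimate = q, std_error = 0.2,
                             p_value = NA_real_),
              df_residual = 30,
              class = c("misslong_fit", "tbl_df", "tbl", "data.frame")))
  pe <- rubin_pool(fits)
  expect_equal(pe$estimate, 1.0, tolerance = 1e-12)
  expect_equal(pe$ubar, 0.04, tolerance = 1e-12)
  expect_equal(pe$b, 0.025, tolerance = 1e-12)
  expect_equal(pe$t_total, 0.07, tolerance = 1e-12)
  expect_equal(pe$df, 4 * (1 + 0.04 / (1.2 * 0.025))^2, tolerance = 1e-12)
  expect_gte(pe$t_total, pe$ubar)

  # identical estimates: B = 0, complete-data df, flagged
  same <- purrr::map(1:3, ~ fits[[1]])
  pe0 <- rubin_pool(same)
  expect_equal(pe0$b, 0)
  expect_equal(pe0$t_total, pe0$ubar)
  expect_equal(pe0$df, 30)
  expect_true(pe0$b_zero)

  expect_error(rubin_pool(fits[1]), "m >= 2")
})

test_that("pooled estimates collapse to the complete-data fit when nothing is missing", {
  coh <- reference_cohort(seed = 5, missingness = FALSE)
  imps <- emb_impute(coh, m = 5, seed = 6)
  fits <- purrr::map(imps$imputations, function(d) {
    d <- dplyr::filter(d, visit == 2)
    d$arm <- as.numeric(d$group == "ART-Early")
    glm_fit(d, "cd4_pct", family = "normal", covariates = "arm")
  })
  pe <- rubin_pool(fits, term = "arm")
  single <- {
    d <- dplyr::filter(coh, visit == 2)
    d$arm <- as.numeric(d$group == "ART-Early")
    glm_fit(d, "cd4_pct", family = "normal", covariates = "arm")
  }
  expect_equal(pe$estimate, single$estimate[single$term == "arm"])
  expect_equal(sqrt(pe$t_total), single$std_error[single$term == "arm"])
})

test_that("stepwise selection keeps a strong signal and handles no candidates", {
  withr::with_seed(7, {
    coh <- reference_cohort(seed = 8, missingness = FALSE)
    # plant a strong arm signal in one variable, refresh others as noise
    coh$cd95_pct <- 50 + 20 * (coh$group == "ART-Early") + rnorm(nrow(coh), 0, 5)
    coh$nk_mature <- runif(nrow(coh), 30, 70)
    coh$il7 <- runif(nrow(coh), 1, 9)
    masked <- inject_missingness(coh, missingness_spec(rates = c(flow = 0.2)),
                                 seed = 9)
    imps <- suppressWarnings(emb_impute(masked, m = 3, seed = 10))
    sel <- suppressWarnings(
      stepwise_logistic(imps, candidates = c("cd95_pct", "nk_mature", "il7")))
    expect_true("cd95_pct" %in% sel$selected)
    expect_s3_class(sel$pooled, "pooled_estimate")

    empty <- stepwise_logistic(imps, candidates = character(0))
    expect_length(empty$selected, 0)
    expect_null(empty$pooled)
  })
})
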