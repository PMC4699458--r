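#' Arm-effect recovery experiment
#'
#' Monte-Carlo calibration of the two inference routes on the reference
#' cohort geometry (24/42 enrolled, 12/22 retained). Each replicate generates
#' a cohort in which the visit-2 CD4% means of the two arms are equalised and
#' a known additive arm effect `delta` is injected for ART-Early; standard
#' panel missingness is applied and the response itself is masked MCAR at the
#' flow-panel rate, so both routes must handle missing responses. The
#' replicate is then analysed by (a) bootstrap-EM multiple imputation with
#' Rubin pooling and (b) the one-step Bayesian sampler, and each route's 95%
#' interval is checked for coverage of `delta`.
#'
#' @param n_reps Number of replicates.
#' @param delta Injected arm effect on CD4% (percentage points).
#' @param response_rate MCAR masking rate applied to the response.
#' @param m Imputations per replicate.
#' @param n_iter,burn_in MCMC length per chain for the Bayesian route.
#' @param seed Integer base seed.
#' @return A tibble with one row per replicate: `rep`, `mi_est`, `mi_lower`,
#'   `mi_upper`, `mi_covered`, `bayes_est`, `bayes_lower`, `bayes_upper`,
#'   `bayes_covered`.
#' @export
coverage_experiment <- function(n_reps = 200L, delta = 4, response_rate = 0.31,
                                m = 5L, n_iter = 10000L, burn_in = 4000L,
                                seed = 1L) {
  specs <- variable_specs()
  base <- specs$mean[specs$variable == "cd4_pct" & specs$group == "ART-Def" &
                       specs$visit == 2L]
  specs$mean[specs$variable == "cd4_pct" & specs$group == "ART-Early" &
               specs$visit == 2L] <- base + delta

  purrr::map_dfr(seq_len(n_reps), function(r) {
    rs <- seed + 1000L * r
    coh <- generate_cohort(cohort_config(seed = rs), specs = specs)
    coh <- inject_missingness(coh, missingness_spec(), seed = rs + 1L)
    both <- coh |>
      dplyr::filter(.data$group != "HEU") |>
      dplyr::count(.data$subject_id) |>
      dplyr::filter(.data$n == 2L) |>
      dplyr::pull("subject_id")
    tb <- dplyr::filter(coh, .data$subject_id %in% both)
    tb <- with_seed(rs + 2L, {
      hit <- runif(nrow(tb)) < response_rate
      tb$cd4_pct[hit] <- NA_real_
      tb
    })

    imps <- emb_impute(tb, m = m, seed = rs + 3L)
    fits <- purrr::map(imps$imputations, function(d) {
      d <- dplyr::filter(d, .data$visit == 2L)
      d$arm <- as.numeric(d$group == "ART-Early")
      glm_fit(d, "cd4_pct", family = "normal", covariates = "arm")
    })
    pooled <- rubin_pool(fits, term = "arm")
    half <- stats::qt(0.975, pooled$df) * sqrt(pooled$t_total)
    mi_lo <- pooled$estimate - half
    mi_hi <- pooled$estimate + half

    v2 <- dplyr::filter(tb, .data$visit == 2L)
    v2$arm <- as.numeric(v2$group == "ART-Early")
    bf <- fit_bayes(v2, "cd4_pct", "arm", likelihood = "normal",
                    n_iter = n_iter, burn_in = burn_in, n_chains = 2L,
                    seed = rs + 4L)
    arm <- bf$summary[bf$summary$term == "arm", ]

    tibble::tibble(
      rep = r,
      mi_est = pooled$estimate, mi_lower = mi_lo, mi_upper = mi_hi,
      mi_covered = delta >= mi_lo & delta <= mi_hi,
      bayes_est = arm$mean, bayes_lower = arm$q2.5, bayes_upper = arm$q97.5,
      bayes_covered = delta >= arm$q2.5 & delta <= arm$q97.5
    )
  })
}

# one synthetic replicate for the Little's-test operating characteristics:
# p = 6 exchangeably correlated normals in two 3-variable panels
little_replicate <- function(n, mechanism = c("MCAR", "MNAR", "MAR"),
                             rate = 0.3, slope = 0) {
  mechanism <- match.arg(mechanism)
  x <- mvtnorm::rmvnorm(n, sigma = diag(6) + 0.3)
  calib <- function(d) {
    if (slope == 0) return(rep(rate, n))
    a <- uniroot(function(a) mean(plogis(a + slope * d)) - rate,
                 c(-40, 40))$root
    plogis(a + slope * d)
  }
  if (mechanism == "MCAR") {
    x[runif(n) < rate, 1:3] <- NA
    x[runif(n) < rate, 4:6] <- NA
  } else if (mechanism == "MAR") {
    # fully observed driver (variable 1) masks the second panel
    pm <- calib(scale(x[, 1])[, 1])
    x[runif(n) < pm, 4:6] <- NA
  } else {
    # self-masking of half the variables, cell level
    for (j in 1:3) {
      pm <- calib(scale(x[, j])[, 1])
      x[runif(n) < pm, j] <- NA
    }
  }
  x[rowSums(!is.na(x)) > 0, , drop = FALSE]
}

#' Operating characteristics of Little's MCAR test
#'
#' Simulates the test's empirical size (under MCAR panel masking) or its
#' power curve (under MAR or self-masking MNAR) on a six-variable
#' exchangeably correlated normal population split into two assay-style
#' panels.
#'
#' @param n_reps Replicates per condition.
#' @param n Rows per replicate.
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param rate Marginal masking rate.
#' @param slopes Logistic slope(s) on the standardised driver; the size
#'   experiment uses 0.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return A tibble with one row per slope: `slope`, `rejection_rate`,
#'   `n_reps`.
#' @export
little_calibration <- function(n_reps = 1000L, n = 100L, mechanism = "MCAR",
                               rate = 0.3, slopes = 0, alpha = 0.05,
                               seed = 1L) {
  purrr::map_dfr(slopes, function(sl) {
    rej <- with_seed(seed + round(1000 * sl), {
      mean(purrr::map_lgl(seq_len(n_reps), function(r) {
        x <- little_replicate(n, mechanism, rate, sl)
        suppressWarnings(little_mcar_test(x)$p_value) < alpha
      }))
    })
    tibble::tibble(slope = sl, rejection_rate = rej, n_reps = n_reps)
  })
}
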