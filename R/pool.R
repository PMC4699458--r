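#' @importFrom stats pt lm glm coef vcov quasipoisson as.formula step median
#'   binomial reformulate
NULL

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance (Welch) t-test computed directly from group means, SDs
#' and sizes, as used for baseline comparisons when only summary statistics
#' are tabulated. Vectorised over rows.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble with `statistic` (t), `df` (Welch-Satterthwaite) and
#'   `p_value` (two-sided).
#' @export
#' @examples
#' welch_t(42.5, 6.8, 23, 36.0, 8.5, 66)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  ml_assert(all(n1 >= 2) && all(n2 >= 2), "group sizes must be >= 2")
  ml_assert(all(sd1 > 0) && all(sd2 > 0), "SDs must be > 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(statistic = t, df = df,
                 p_value = 2 * pt(-abs(t), df))
}

#' Bonferroni significance flags
#'
#' Flags each p-value significant iff `p < alpha / m`, where `m` is the size
#' of the test family (default: the number of p-values supplied).
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise error rate.
#' @param m Family size.
#' @return Logical vector of flags.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  ml_assert(length(p_values) > 0, "empty p-value input")
  ml_assert(all(p_values >= 0 & p_values <= 1), "p-values must lie in [0, 1]")
  p_values < alpha / m
}

#' Per-dataset GLM fit under a normal or Poisson assumption
#'
#' Fits `response ~ covariates` on one complete dataset. `family = "normal"`
#' is ordinary least squares with classical standard errors. `family =
#' "poisson"` is a quasi-Poisson log-link fit (dispersion-scaled SEs, so the
#' non-integer percent-scale responses are handled honestly); with a single
#' two-level arm covariate its arm coefficient is the log of the ratio of
#' fitted group means. Response codings for the Poisson mode: `"percent"`
#' (default; the raw percent-scale value) or `"log100"` (the literal
#' `log(100 * proportion)` transformation).
#'
#' @param data A complete data frame.
#' @param response Response column name.
#' @param family `"normal"` or `"poisson"`.
#' @param covariates Character vector of covariate column names (default
#'   `"arm"`).
#' @param coding Poisson response coding, `"percent"` or `"log100"`.
#' @param on_nonpositive For the log-link modes, `"error"` (default) or
#'   `"shift"` (adds the minimum shift making the response positive, with a
#'   warning); never silent.
#' @return Object of class `misslong_fit`: a tibble with `term`, `estimate`,
#'   `std_error`, `p_value`, and attributes `family`, `response`, `n`,
#'   `df_residual`.
#' @export
glm_fit <- function(data, response, family = c("normal", "poisson"),
                    covariates = "arm", coding = c("percent", "log100"),
                    on_nonpositive = c("error", "shift")) {
  family <- match.arg(family)
  coding <- match.arg(coding)
  on_nonpositive <- match.arg(on_nonpositive)
  ml_assert(response %in% names(data), "response column not found")
  ml_assert(all(covariates %in% names(data)), "covariate column not found")
  use <- data[c(response, covariates)]
  ml_assert(!anyNA(use[[response]]),
            "glm_fit requires a complete response (impute first)")
  y <- use[[response]]

  if (family == "normal") {
    fit <- lm(reformulate(covariates, response), data = use)
    ct <- summary(fit)$coefficients
  } else {
    if (coding == "log100") {
      if (any(y <= 0)) {
        if (on_nonpositive == "error")
          ml_abort("non-positive response under log100 coding", "nonpositive")
        shift <- abs(min(y)) + 0.5
        rlang::warn(sprintf("shifting response by %+.3g before log100 coding",
                            shift))
        y <- y + shift
      }
      use[[response]] <- log(y) # response already on the 100*proportion scale
      y <- use[[response]]
    }
    if (any(y < 0)) {
      if (on_nonpositive == "error")
        ml_abort("negative response under the log link", "nonpositive")
      shift <- abs(min(y)) + 0.5
      rlang::warn(sprintf("shifting response by %+.3g for the log link", shift))
      use[[response]] <- y + shift
    }
    fit <- suppressWarnings(
      glm(reformulate(covariates, response), data = use,
          family = quasipoisson(link = "log")))
    ct <- summary(fit)$coefficients
  }
  out <- tibble::tibble(
    term = rownames(ct), estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]), p_value = unname(ct[, 4])
  )
  structure(out, family = family, response = response, n = nrow(use),
            df_residual = fit$df.residual, coding = if (family == "poisson") coding,
            class = c("misslong_fit", class(out)))
}

#' Rubin's-rules pooling of per-imputation fits
#'
#' Combines `m` per-imputation estimates of the same model: pooled point
#' estimate `Qbar = mean(Q_i)`; within-imputation variance `Ubar =
#' mean(SE_i^2)`; between-imputation variance `B = var(Q_i)` (denominator
#' `m - 1`); total variance `T = Ubar + (1 + 1/m) B`; degrees of freedom
#' `(m - 1)(1 + Ubar / ((1 + 1/m) B))^2`; and a two-sided p from the t
#' reference. When `B = 0` (identical estimates, e.g. nothing was missing)
#' the total variance collapses to `Ubar` and the complete-data residual df
#' is used, flagged via `b_zero`.
#'
#' @param fits List of `misslong_fit` objects (or an `imputation_set`'s fits)
#'   from the identical model over `m >= 2` imputations.
#' @param term Term(s) to pool; default all shared terms.
#' @return Object of class `pooled_estimate`: tibble with `term`, `estimate`
#'   (Qbar), `ubar`, `b`, `t_total`, `df`, `statistic`, `p_value`, `m`,
#'   `b_zero`.
#' @export
#' @examples
#' # five imputations, hand-checkable pooling arithmetic
#' fits <- lapply(c(1.0, 1.2, 0.8, 1.1, 0.9), function(q)
#'   structure(tibble::tibble(term = "arm", estimate = q,
#'                            std_error = 0.2, p_value = NA),
#'             df_residual = 30, class = c("misslong_fit", "tbl_df",
#'                                         "tbl", "data.frame")))
#' rubin_pool(fits)
rubin_pool <- function(fits, term = NULL) {
  ml_assert(is.list(fits) && length(fits) >= 2, "need m >= 2 fits to pool")
  m <- length(fits)
  terms0 <- fits[[1]]$term
  ml_assert(all(purrr::map_lgl(fits, ~ identical(.x$term, terms0))),
            "all fits must share the identical model terms")
  term <- term %||% terms0
  df_com <- attr(fits[[1]], "df_residual") %||% Inf
  rows <- purrr::map(term, function(tm) {
    q <- purrr::map_dbl(fits, ~ .x$estimate[.x$term == tm])
    se <- purrr::map_dbl(fits, ~ .x$std_error[.x$term == tm])
    qbar <- mean(q)
    ubar <- mean(se^2)
    b <- var(q)
    t_total <- ubar + (1 + 1 / m) * b
    b_zero <- b <= .Machine$double.eps * max(1, ubar)
    df <- if (b_zero) df_com else (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
    stat <- qbar / sqrt(t_total)
    tibble::tibble(term = tm, estimate = qbar, ubar = ubar, b = b,
                   t_total = t_total, df = df, statistic = stat,
                   p_value = 2 * pt(-abs(stat), df), m = m, b_zero = b_zero)
  })
  structure(dplyr::bind_rows(rows),
            class = c("pooled_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Backward stepwise logistic selection across imputations
#'
#' Within each completed dataset, fits a logistic regression of the binary
#' outcome on the candidate variables and runs backward elimination by AIC
#' ([stats::step()]). The final variable set is decided by majority vote:
#' variables retained in more than half the imputations. That set is refit in
#' every imputation and Rubin-pooled. Apparent separation (any |coefficient|
#' above 15 on standardised candidates) triggers a warning and a
#' ridge-stabilised refit.
#'
#' @param imps An `imputation_set`.
#' @param outcome Binary outcome column (default `"arm"`: ART-Early vs
#'   ART-Def; HEU rows are dropped).
#' @param candidates Character vector of candidate predictor columns.
#' @return List with `selected` (character), `votes` (tibble), `pooled`
#'   (a `pooled_estimate` for the final model, `NULL` if empty).
#' @export
stepwise_logistic <- function(imps, outcome = "arm", candidates) {
  ml_assert(inherits(imps, "imputation_set"), "`imps` must be an imputation_set")
  prep <- function(tb) {
    if (outcome == "arm") {
      tb <- dplyr::filter(tb, .data$group != "HEU")
      tb$arm <- as.numeric(tb$group == "ART-Early")
    }
    tb[candidates] <- lapply(tb[candidates], function(x) as.numeric(scale(x)))
    tb
  }
  kept <- purrr::map(imps$imputations, function(tb) {
    tb <- prep(tb)
    if (length(candidates) == 0) return(character())
    full <- suppressWarnings(
      glm(reformulate(candidates, outcome), data = tb, family = binomial()))
    red <- suppressWarnings(step(full, direction = "backward", trace = 0))
    setdiff(names(coef(red)), "(Intercept)")
  })
  votes <- tibble::tibble(variable = candidates,
                          votes = purrr::map_int(candidates, function(v)
                            sum(purrr::map_lgl(kept, ~ v %in% .x))))
  selected <- votes$variable[votes$votes > imps$m / 2]
  pooled <- NULL
  if (length(selected) > 0) {
    fits <- purrr::map(imps$imputations, function(tb) {
      tb <- prep(tb)
      fit <- suppressWarnings(
        glm(reformulate(selected, outcome), data = tb, family = binomial()))
      if (any(abs(coef(fit)[-1]) > 15)) {
        rlang::warn("possible separation; ridge-stabilised logistic refit")
        fit <- ridge_logistic(tb, outcome, selected)
        ct <- fit$summary_table
        rownames(ct) <- names(fit$coefficients)
      } else {
        ct <- summary(fit)$coefficients
      }
      structure(tibble::tibble(term = rownames(ct), estimate = ct[, 1],
                               std_error = ct[, 2], p_value = ct[, 4]),
                df_residual = fit$df.residual,
                class = c("misslong_fit", "tbl_df", "tbl", "data.frame"))
    })
    pooled <- rubin_pool(fits)
  }
  list(selected = selected, votes = votes, pooled = pooled)
}

# small-L2-penalty logistic fit by IRLS, used only when ML separates
ridge_logistic <- function(data, outcome, predictors, lambda = 0.5) {
  x <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  y <- data[[outcome]]
  beta <- numeric(ncol(x))
  pen <- diag(c(0, rep(lambda, length(predictors))))
  for (i in 1:50) {
    eta <- as.numeric(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    h <- crossprod(x * w, x) + pen
    beta_new <- solve(h, crossprod(x * w, z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  vc <- solve(h)
  se <- sqrt(diag(vc))
  est <- as.numeric(beta)
  zstat <- est / se
  list(coefficients = stats::setNames(est, colnames(x)),
       df.residual = nrow(x) - ncol(x),
       summary_table = cbind(est, se, zstat, 2 * pnorm(-abs(zstat))))
}
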