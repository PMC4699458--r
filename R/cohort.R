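#' @importFrom stats plogis qlnorm rlnorm uniroot optim runif quantile
NULL

# analytic mean/sd of a normal truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  lam <- (dnorm(al) - dnorm(be)) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# solve for latent (mu, sigma) so the truncated-normal moments hit the
# target (m, s); when the bounds are far (>5 sd) the identity is exact enough.
# Solutions are cached: the calibration table is fixed, the solve is not cheap.
.truncnorm_cache <- new.env(parent = emptyenv())

match_truncnorm <- function(m, s, a, b) {
  if (s < 1e-6 || (m - a > 5 * s && b - m > 5 * s)) {
    return(c(mu = m, sigma = s))
  }
  key <- paste(m, s, a, b, sep = "|")
  hit <- .truncnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mom[1] - m)^2 / s^2 + (mom[2] - s)^2 / s^2
  }
  fit <- optim(c(m, log(s)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  .truncnorm_cache[[key]] <- out
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws one row per subject-visit from a Gaussian-copula scheme: a latent
#' multivariate normal with exchangeable correlation `rho` across the T-cell
#' variables (other variables independent) is pushed through each variable's
#' truncated-normal marginal, whose latent parameters are moment-matched so
#' the sampled mean and SD reproduce the per-(group, visit) calibration
#' targets. IL-7 is additionally interval-censored to its ELISA detection
#' range (0.25-16 pg/mL). Visit-2 subjects are a random subset of each arm's
#' visit-1 subjects; ART-initiation days are drawn from the config's
#' quantile-matched log-normals.
#'
#' @param config A [cohort_config()].
#' @param specs A [variable_specs()] calibration table. If `config` carries an
#'   `arm_effect`, it is applied here unless `specs` is supplied explicitly.
#' @return A tibble, one row per subject-visit, with columns `subject_id`,
#'   `group`, `visit`, `age_days`, `art_init_day`, then the 17 measurement
#'   columns. No cell is missing. Attributes `seed` and `config_hash` record
#'   provenance.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' dplyr::count(coh, group, visit)
generate_cohort <- function(config = cohort_config(), specs = NULL) {
  ml_assert(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  specs <- specs %||% variable_specs(arm_effect = config$arm_effect)
  validate_variable_specs(specs)
  vars <- unique(specs$variable)
  ml_assert(length(vars) == 17L && !anyNA(match(specs$variable, vars)),
            "specs must cover all 17 variables")

  with_seed(config$seed, {
    rows <- list()
    subj_counter <- 0L
    for (g in names(config$n)) {
      n1 <- config$n[[g]][1]; n2 <- config$n[[g]][2]
      if (n1 == 0L) next
      ids <- sprintf("%s-%03d", c(`ART-Def` = "AD", `ART-Early` = "AE",
                                  HEU = "HEU")[[g]], subj_counter + seq_len(n1))
      subj_counter <- subj_counter + n1
      retained <- if (n2 > 0) sample(ids, n2) else character()
      art <- if (g %in% names(config$art_init)) {
        p <- config$art_init[[g]]
        round(rlnorm(n1, p$meanlog, p$sdlog))
      } else rep(NA_real_, n1)
      for (v in c(1L, 2L)) {
        use <- if (v == 1L) ids else retained
        if (!length(use)) next
        ag <- config$visit_age[[g]][[as.character(v)]]
        age <- round(truncnorm::rtruncnorm(length(use), a = 14, mean = ag[1],
                                           sd = ag[2]))
        vals <- draw_measurements(length(use), g, v, specs, vars,
                                  config$rho, config$tcell_vars)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = use, group = g, visit = v, age_days = age,
          art_init_day = art[match(use, ids)]
        ) |> dplyr::bind_cols(vals)
      }
    }
    out <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$group, .data$subject_id, .data$visit)
    attr(out, "seed") <- config$seed
    attr(out, "config_hash") <- rlang::hash(config)
    out
  })
}

draw_measurements <- function(n, group, visit, specs, vars, rho, tcell_vars) {
  p <- length(vars)
  corr <- diag(p)
  idx <- match(intersect(tcell_vars, vars), vars)
  corr[idx, idx] <- rho
  diag(corr) <- 1
  z <- mvtnorm::rmvnorm(n, sigma = corr)
  u <- pnorm(z)
  out <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
  cell <- specs[specs$group == group & specs$visit == visit, ]
  for (j in seq_len(p)) {
    row <- cell[cell$variable == vars[j], ]
    ml_assert(nrow(row) == 1, paste0("no spec cell for ", vars[j], " / ",
                                     group, " visit ", visit))
    lat <- match_truncnorm(row$mean, row$sd, row$lower, row$upper)
    if (lat["sigma"] < 1e-6) {
      x <- rep(min(max(lat["mu"], row$lower), row$upper), n)
    } else {
      # truncated-normal quantile transform of the copula uniforms
      pa <- pnorm(row$lower, lat["mu"], lat["sigma"])
      pb <- pnorm(row$upper, lat["mu"], lat["sigma"])
      x <- qnorm(pa + u[, j] * (pb - pa), lat["mu"], lat["sigma"])
      x <- pmin(pmax(x, row$lower), row$upper) # guard qnorm edge cases
    }
    if (!is.na(row$censor_lower)) x <- pmax(x, row$censor_lower)
    if (!is.na(row$censor_upper)) x <- pmin(x, row$censor_upper)
    out[, j] <- x
  }
  tibble::as_tibble(out)
}

#' Inject missingness into a cohort table
#'
#' Masks measurement cells according to a [missingness_spec()]. Under the
#' default panel-level masking a hit removes every variable of that panel for
#' that subject-visit, emulating a failed blood draw. MAR and MNAR intercepts
#' are calibrated on the realised driver values so the marginal masked
#' fraction matches the target rate. Observed values are never altered.
#'
#' @param table A complete (or partially masked) cohort tibble.
#' @param spec A [missingness_spec()].
#' @param seed Integer seed for the masking draws.
#' @return The cohort tibble with masked cells set to `NA`. Attribute
#'   `missingness` records the spec and realised per-panel rates.
#' @export
inject_missingness <- function(table, spec = missingness_spec(), seed = NULL) {
  ml_assert(inherits(spec, "missingness_spec"), "`spec` must be a missingness_spec")
  specs <- variable_specs()
  panels <- split(specs$variable[!duplicated(specs$variable)],
                  specs$panel[!duplicated(specs$variable)])
  if (spec$mechanism == "MAR") {
    ml_assert(spec$mar_driver %in% names(table), "MAR driver column not found")
    ml_assert(!anyNA(table[[spec$mar_driver]]),
              "MAR driver must be fully observed (a maskable driver is rejected)")
  }

  with_seed(seed, {
    n <- nrow(table)
    realised <- c()
    for (panel in names(panels)) {
      rate <- spec$rates[panel]
      if (is.na(rate) || rate <= 0) next
      pvars <- intersect(panels[[panel]], names(table))
      if (!length(pvars)) next
      if (spec$level == "panel" || spec$mechanism != "MNAR") {
        driver <- switch(spec$mechanism,
          MCAR = NULL,
          MAR = scale(table[[spec$mar_driver]])[, 1],
          # panel-level MNAR: the panel's first variable anchors the mechanism
          MNAR = scale(table[[pvars[1]]])[, 1])
        pmask <- mask_prob(n, rate, driver, spec$slope)
        hit <- runif(n) < pmask
        if (spec$level == "panel") {
          for (v in pvars) table[[v]][hit] <- NA_real_
        } else {
          for (v in pvars) {
            pm <- mask_prob(n, rate, driver, spec$slope)
            table[[v]][runif(n) < pm] <- NA_real_
          }
        }
      } else { # cell-level MNAR: each variable's own value drives its mask
        for (v in pvars) {
          driver <- scale(table[[v]])[, 1]
          pm <- mask_prob(n, rate, driver, spec$slope)
          table[[v]][runif(n) < pm] <- NA_real_
        }
      }
      masked <- rowSums(is.na(table[pvars])) == length(pvars)
      realised[panel] <- mean(masked)
    }
    attr(table, "missingness") <- list(spec = spec, realised = realised)
    table
  })
}

# per-row masking probability with the intercept calibrated so the
# marginal rate equals `rate` on the realised driver values
mask_prob <- function(n, rate, driver, slope) {
  if (is.null(driver) || slope == 0) return(rep(rate, n))
  driver[is.na(driver)] <- 0
  f <- function(a) mean(plogis(a + slope * driver)) - rate
  a <- uniroot(f, c(-40, 40))$root
  plogis(a + slope * driver)
}

#' Packaged deterministic cohort fixture
#'
#' A fixed-seed cohort with the reference geometry -- 24/42 infected infants
#' per arm at visit 1, of whom 12/22 return at visit 2, plus 23 single-visit
#' HEU controls (66 infected at visit 1; 34 with both visits) -- calibrated to
#' the observed summary table, with MCAR panel masking at the per-assay rates
#' (CD4 0%, ELISA 20%, flow 31%, VL 45%).
#'
#' @param seed Integer seed (default 20151215).
#' @param missingness Logical; mask panels (default) or return complete data.
#' @return A cohort tibble.
#' @export
reference_cohort <- function(seed = 20151215L, missingness = TRUE) {
  coh <- generate_cohort(cohort_config(seed = seed))
  if (missingness) {
    coh <- inject_missingness(coh, missingness_spec(), seed = seed + 1L)
  }
  coh
}

measurement_vars <- function(table) {
  intersect(unique(variable_specs()$variable), names(table))
}

#' Write / read a cohort table as CSV
#'
#' RFC 4180 CSV with a header row; missing cells are written as empty fields.
#' `read_cohort()` validates the schema (known columns, group labels, visit
#' codes, bounds) and fails with an informative error on malformed input.
#'
#' @param table A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  ml_assert(file.exists(path) && file.size(path) > 0,
            "empty or absent cohort file", "io")
  tb <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  need <- c("subject_id", "group", "visit", "age_days")
  miss <- setdiff(need, names(tb))
  ml_assert(length(miss) == 0,
            paste0("cohort file lacks required columns: ",
                   paste(miss, collapse = ", ")), "io")
  specs <- variable_specs()
  known <- c(need, "art_init_day", unique(specs$variable))
  extra <- setdiff(names(tb), known)
  ml_assert(length(extra) == 0,
            paste0("unknown columns in cohort file: ",
                   paste(extra, collapse = ", ")), "io")
  ml_assert(all(tb$visit %in% c(1L, 2L)), "visit must be 1 or 2", "io")
  ml_assert(all(tb$group %in% c("ART-Def", "ART-Early", "HEU")),
            "unknown group label", "io")
  ml_assert(!anyDuplicated(tb[c("subject_id", "visit")]),
            "duplicate (subject, visit) keys", "io")
  for (v in intersect(unique(specs$variable), names(tb))) {
    b <- specs[specs$variable == v, c("lower", "upper")][1, ]
    x <- tb[[v]]
    bad <- which(!is.na(x) & (x < b$lower | x > b$upper))
    ml_assert(length(bad) == 0,
              paste0("value out of bounds in column ", v, ", row ", bad[1]),
              "io")
  }
  tb
}
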