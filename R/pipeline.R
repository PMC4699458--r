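#' End-to-end missing-data analysis pipeline
#'
#' Runs the full analysis tree on a (generated or supplied) cohort:
#' simulate -> missingness diagnosis (map + Little's MCAR test) -> multiple
#' imputation (m completed sets) -> Rubin-pooled GLMs under normal and
#' Poisson assumptions -> one-step Bayesian fits under both assumptions ->
#' cross-method and cross-distribution concordance, plus overimputation,
#' R-hat and DIC diagnostics. Any stage failure marks that stage failed and
#' skips its dependents; the report records every stage's status.
#'
#' The arm-effect models follow the reference design: per response variable,
#' the visit-2 records of infected subjects seen at both visits, with the
#' treatment arm (ART-Early vs ART-Def) as the single covariate. Baseline
#' comparisons (visit 1, infected vs HEU) use Welch t-tests with a
#' Bonferroni family of all tested rows.
#'
#' @param config A [cohort_config()].
#' @param missingness A [missingness_spec()].
#' @param table Optional cohort tibble to analyse instead of simulating.
#' @param m Number of imputations.
#' @param mcmc List of MCMC settings for the Bayesian stage (`n_iter`,
#'   `burn_in`, `n_chains`, `thin`). The default uses a short chain length
#'   suited to the 15-variable sweep; pass larger values for production runs.
#' @param responses Response variables for the arm-effect models; default:
#'   the 15 immune measurements (flow panel + CD4% + IL-7).
#' @param overimpute_variable Representative variable for the overimputation
#'   diagnostic.
#' @param seed Master seed; the whole report is reproducible from it.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         missingness = missingness_spec(),
                         table = NULL, m = 5L,
                         mcmc = list(n_iter = 4000L, burn_in = 1000L,
                                     n_chains = 2L, thin = 1L),
                         responses = NULL,
                         overimpute_variable = "cd27_naive_cd4",
                         seed = NULL) {
  seed <- seed %||% config$seed
  stages <- tibble::tibble(stage = character(), status = character(),
                           message = character())
  note <- function(stage, status, message = "") {
    stages <<- dplyr::add_row(stages, stage = stage, status = status,
                              message = message)
  }
  run_stage <- function(stage, expr) {
    tryCatch({
      out <- force(expr)
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }
  skip_stage <- function(stage) note(stage, "skipped", "upstream failure")

  specs <- variable_specs()
  all_vars <- unique(specs$variable)
  responses <- responses %||%
    setdiff(all_vars[specs$panel[match(all_vars, specs$variable)] %in%
                       c("cd4", "flow", "elisa")], "birth_weight")

  cohort <- run_stage("simulate", {
    if (!is.null(table)) table else {
      cfg <- config; cfg$seed <- seed
      inject_missingness(generate_cohort(cfg), missingness, seed = seed + 1L)
    }
  })
  if (is.null(cohort)) {
    return(new_pipeline_report(stages = stages, seed = seed))
  }

  baseline <- run_stage("baseline", baseline_tests(cohort))

  diag_missing <- run_stage("diagnose", {
    map <- missingness_map(cohort)
    tests <- list(
      visit1 = little_mcar_test(dplyr::filter(cohort, .data$visit == 1L,
                                              .data$group != "HEU"),
                                vars = responses),
      visit2 = little_mcar_test(dplyr::filter(cohort, .data$visit == 2L),
                                vars = responses),
      stacked = little_mcar_test(dplyr::filter(cohort, .data$group != "HEU"),
                                 vars = responses)
    )
    list(map = map, little = tests)
  })

  both_ids <- cohort |>
    dplyr::filter(.data$group != "HEU") |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::pull("subject_id")
  analysis_tb <- dplyr::filter(cohort, .data$subject_id %in% both_ids)

  imps <- run_stage("impute", emb_impute(analysis_tb, m = m, seed = seed + 2L))

  mi_est <- if (is.null(imps)) { skip_stage("fit_mi"); NULL } else {
    run_stage("fit_mi", mi_arm_estimates(imps, responses))
  }

  bayes_est <- run_stage("fit_bayes",
    bayes_arm_estimates(analysis_tb, responses, mcmc, seed = seed + 3L))

  conc <- if (is.null(mi_est) || is.null(bayes_est)) {
    skip_stage("compare"); NULL
  } else {
    run_stage("compare", concordance_tables(mi_est, bayes_est))
  }

  over <- if (is.null(imps)) { skip_stage("overimpute"); NULL } else {
    run_stage("overimpute",
              overimpute(analysis_tb, overimpute_variable, seed = seed + 4L))
  }

  new_pipeline_report(
    meta = list(seed = seed, m = m, mcmc = mcmc, responses = responses,
                config_hash = rlang::hash(config),
                package_version = as.character(utils::packageVersion("misslong"))),
    cohort_summary = summarise_cohort(cohort),
    baseline = baseline,
    missingness = diag_missing,
    mi_estimates = mi_est,
    bayes_estimates = bayes_est,
    concordance = conc,
    overimputation = over,
    stages = stages,
    seed = seed
  )
}

new_pipeline_report <- function(..., stages, seed) {
  structure(c(list(...), list(stages = stages, seed = seed)),
            class = "pipeline_report")
}

summarise_cohort <- function(cohort) {
  vars <- measurement_vars(cohort)
  cohort |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(.data$group, .data$visit, .data$variable) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)), .groups = "drop")
}

# Welch baseline comparisons, infected visit 1 vs HEU, Bonferroni family =
# all tested rows (visit age, birth weight, the immune measurements)
baseline_tests <- function(cohort) {
  v1 <- dplyr::filter(cohort, .data$visit == 1L)
  vars <- c("age_days", setdiff(measurement_vars(cohort), "log10_vl"))
  rows <- purrr::map_dfr(vars, function(v) {
    a <- v1[[v]][v1$group == "HEU"]
    b <- v1[[v]][v1$group != "HEU"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 || sd(a) == 0 || sd(b) == 0) {
      return(tibble::tibble(variable = v, mean_heu = mean(a), sd_heu = sd(a),
                            n_heu = length(a), mean_hiv = mean(b),
                            sd_hiv = sd(b), n_hiv = length(b),
                            p_value = NA_real_))
    }
    wt <- welch_t(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    tibble::tibble(variable = v, mean_heu = mean(a), sd_heu = sd(a),
                   n_heu = length(a), mean_hiv = mean(b), sd_hiv = sd(b),
                   n_hiv = length(b), p_value = wt$p_value)
  })
  ok <- !is.na(rows$p_value)
  rows$significant <- FALSE
  rows$significant[ok] <- bonferroni(rows$p_value[ok], m = nrow(rows))
  rows
}

mi_arm_estimates <- function(imps, responses) {
  purrr::map_dfr(responses, function(resp) {
    purrr::map_dfr(c("normal", "poisson"), function(fam) {
      fits <- purrr::map(imps$imputations, function(tb) {
        tb <- dplyr::filter(tb, .data$visit == 2L)
        tb$arm <- as.numeric(tb$group == "ART-Early")
        glm_fit(tb, resp, family = fam, covariates = "arm")
      })
      pooled <- rubin_pool(fits, term = "arm")
      intercept <- rubin_pool(fits, term = "(Intercept)")
      pred_early <- if (fam == "normal") {
        intercept$estimate + pooled$estimate
      } else {
        exp(intercept$estimate + pooled$estimate)
      }
      tibble::tibble(response = resp, family = fam,
                     estimate = pooled$estimate, se = sqrt(pooled$t_total),
                     p_value = pooled$p_value, df = pooled$df,
                     b = pooled$b, ubar = pooled$ubar,
                     predicted_early = pred_early)
    })
  })
}

bayes_arm_estimates <- function(analysis_tb, responses, mcmc, seed) {
  v2 <- dplyr::filter(analysis_tb, .data$visit == 2L)
  v2$arm <- as.numeric(v2$group == "ART-Early")
  purrr::imap_dfr(stats::setNames(responses, responses), function(resp, nm) {
    purrr::map_dfr(c("normal", "poisson"), function(fam) {
      fit <- fit_bayes(v2, resp, covariates = "arm", likelihood = fam,
                       n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                       n_chains = mcmc$n_chains %||% 2L,
                       thin = mcmc$thin %||% 1L,
                       seed = seed + match(fam, c("normal", "poisson")) +
                         10L * match(resp, responses))
      s <- fit$summary
      arm <- s[s$term == "arm", ]
      int <- s[s$term == "(Intercept)", ]
      pred_early <- if (fam == "normal") int$mean + arm$mean else
        exp(int$mean + arm$mean)
      tibble::tibble(response = resp, family = fam, estimate = arm$mean,
                     se = arm$sd, p_value = arm$p_value,
                     q2.5 = arm$q2.5, q97.5 = arm$q97.5, rhat = arm$rhat,
                     ess = arm$ess, dic = fit$dic$DIC, pd = fit$dic$pD,
                     converged = fit$converged, predicted_early = pred_early)
    })
  })
}

concordance_tables <- function(mi_est, bayes_est) {
  one <- function(a, b, labels) {
    res <- estimate_concordance(a, b, labels = labels)
    dplyr::select(res, "slope", "intercept", "r_squared", "p_value", "n")
  }
  merged <- dplyr::inner_join(mi_est, bayes_est,
                              by = c("response", "family"),
                              suffix = c("_mi", "_bayes"))
  by_fam <- merged |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(function(d, key) dplyr::bind_rows(
      dplyr::mutate(one(d$estimate_mi, d$estimate_bayes, d$response),
                    quantity = "difference", .before = 1),
      dplyr::mutate(one(d$predicted_early_mi, d$predicted_early_bayes,
                        d$response),
                    quantity = "predicted_mean", .before = 1))) |>
    dplyr::ungroup() |>
    dplyr::mutate(comparison = paste0("mi_vs_bayes_", .data$family)) |>
    dplyr::select(-"family")
  within_method <- purrr::map_dfr(
    list(c("mi", "estimate_mi"), c("bayes", "estimate_bayes")),
    function(mm) {
      wide <- merged |>
        dplyr::select("response", "family", est = dplyr::all_of(mm[2])) |>
        tidyr::pivot_wider(names_from = "family", values_from = "est")
      dplyr::mutate(one(wide$poisson, wide$normal, wide$response),
                    quantity = "difference",
                    comparison = paste0(mm[1], "_normal_vs_poisson"))
    })
  dplyr::bind_rows(by_fam, within_method) |>
    dplyr::relocate("comparison", "quantity")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  print(x$stages)
  if (!is.null(x$concordance)) {
    cat("\nConcordance:\n")
    print(x$concordance)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serialises the report as machine-readable JSON plus a human-readable
#' Markdown summary (same path with extension `.md`). The JSON is written
#' with full floating-point precision, so a fixed-seed run reproduces the
#' file byte-for-byte.
#'
#' @param report A `pipeline_report`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ml_assert(inherits(report, "pipeline_report"), "not a pipeline_report")
  payload <- list(
    schema_version = "1.0",
    meta = report$meta,
    stages = report$stages,
    cohort_summary = report$cohort_summary,
    baseline = report$baseline,
    missingness_rates = if (!is.null(report$missingness))
      report$missingness$map$rates,
    little_tests = if (!is.null(report$missingness))
      purrr::imap_dfr(report$missingness$little, function(lt, nm)
        tibble::tibble(subset = nm, d2 = lt$d2, df = lt$df,
                       p_value = lt$p_value, n_patterns = lt$n_patterns,
                       inapplicable = lt$inapplicable)),
    mi_estimates = report$mi_estimates,
    bayes_estimates = report$bayes_estimates,
    concordance = report$concordance,
    overimputation_coverage = if (!is.null(report$overimputation))
      report$overimputation$coverage
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  md <- c(
    "# Pipeline report", "",
    paste0("Seed: ", report$seed), "",
    "## Stages", "",
    md_table(report$stages),
    if (!is.null(report$mi_estimates)) c(
      "", "## Multiple-imputation arm effects", "",
      md_table(dplyr::mutate(report$mi_estimates,
                             dplyr::across(dplyr::where(is.numeric),
                                           ~ signif(.x, 4))))),
    if (!is.null(report$bayes_estimates)) c(
      "", "## Bayesian arm effects", "",
      md_table(dplyr::mutate(report$bayes_estimates,
                             dplyr::across(dplyr::where(is.numeric),
                                           ~ signif(.x, 4))))),
    if (!is.null(report$concordance)) c(
      "", "## Concordance", "",
      md_table(dplyr::mutate(report$concordance,
                             dplyr::across(dplyr::where(is.numeric),
                                           ~ signif(.x, 4)))))
  )
  writeLines(md, sub("\\.json$", ".md", path))
  invisible(path)
}

md_table <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("(empty)")
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
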