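#' Calibrated variable specifications for the synthetic cohort
#'
#' Returns the per-variable, per-(group, visit) calibration table used by
#' [generate_cohort()]: one row per variable x group x visit cell, carrying the
#' target mean and SD on the natural scale, the variable's hard bounds, its
#' measurement scale and the assay panel it travels with. Defaults reproduce
#' the observed summary statistics of a two-arm infant ART cohort
#' (deferred vs early initiation) with a single-visit HIV-exposed-uninfected
#' (HEU) control group: 12 flow-cytometry percentages plus CD38 mean
#' fluorescence intensity (the flow panel), CD4+ T-cell % (its own priority
#' assay, never missing), serum IL-7 by ELISA (detection range 0.25-16 pg/mL),
#' log10 viral load, and birth weight.
#'
#' Panels matter because missingness in this setting is specimen-driven: a
#' failed or insufficient blood draw removes a whole assay panel for that
#' visit, not individual cells. See [missingness_spec()].
#'
#' @param arm_effect Optional named numeric vector of additive shifts applied
#'   to the ART-Early visit-2 means (natural scale), e.g.
#'   `c(cd4_pct = 4)`. Names must be variable names.
#' @return A tibble with columns `variable`, `panel`, `scale`, `lower`,
#'   `upper`, `censor_lower`, `censor_upper`, `group`, `visit`, `mean`, `sd`.
#' @export
#' @examples
#' specs <- variable_specs()
#' dplyr::filter(specs, variable == "cd4_pct")
variable_specs <- function(arm_effect = NULL) {
  meta <- tibble::tribble(
    ~variable,         ~panel,     ~scale,         ~lower, ~upper,
    "birth_weight",    "clinical", "grams",        300,    6500,
    "cd4_pct",         "cd4",      "percent",      0,      100,
    "cd38_pct",        "flow",     "percent",      0,      100,
    "hladr_pct",       "flow",     "percent",      0,      100,
    "cd95_pct",        "flow",     "percent",      0,      100,
    "nk_mature",       "flow",     "percent",      0,      100,
    "nk_immature",     "flow",     "percent",      0,      100,
    "pdc",             "flow",     "percent",      0,      100,
    "cd28_naive_cd4",  "flow",     "percent",      0,      100,
    "cd27_naive_cd4",  "flow",     "percent",      0,      100,
    "cd28_naive_cd8",  "flow",     "percent",      0,      100,
    "cd27_naive_cd8",  "flow",     "percent",      0,      100,
    "cm_cd4",          "flow",     "percent",      0,      100,
    "cm_cd8",          "flow",     "percent",      0,      100,
    "cd38_mfi",        "flow",     "mfi",          0,      10000,
    "il7",             "elisa",    "pg_per_ml",    0,      50,
    "log10_vl",        "vl",       "log10_copies", 1.3,    8
  )

  # observed per-cell moments: ART-Def / ART-Early at visits 1-2, HEU visit 1
  # (HEU log10 VL pinned at the assay floor: uninfected controls)
  cells <- tibble::tribble(
    ~variable,        ~ad1_m, ~ad1_s, ~ae1_m, ~ae1_s, ~ad2_m, ~ad2_s, ~ae2_m, ~ae2_s, ~heu_m, ~heu_s,
    "birth_weight",   2962.9,  551.7, 2930.2,  396.3, 2727.1,  390.4, 2895.5,  405.9,   2573,    703,
    "cd4_pct",          32.9,    7.9,   37.7,    8.4,   34.5,    7.6,   37.9,    6.0,   42.5,    6.8,
    "cd38_pct",         99.1,    0.8,   97.6,    2.0,   97.8,    3.8,   97.7,    2.5,   97.8,    2.2,
    "hladr_pct",        38.0,   17.6,   10.9,    8.8,   22.9,   19.7,   21.9,   16.7,    8.0,    8.8,
    "cd95_pct",         93.4,    7.7,   67.7,   27.5,   87.0,   11.5,   73.4,   22.3,   84.3,   19.4,
    "nk_mature",        55.4,   16.5,   52.4,   16.5,   62.4,    7.7,   60.7,   16.9,   60.3,   15.7,
    "nk_immature",       3.1,    3.4,    5.4,    5.4,    2.8,    1.9,    4.4,    5.8,    3.2,    2.3,
    "pdc",               0.3,    0.1,    0.3,    0.2,    0.4,    0.7,    0.4,    0.4,    0.2,    0.3,
    "cd28_naive_cd4",   76.1,    9.5,   75.7,    8.7,   69.7,    7.4,   70.3,   11.3,   67.4,   10.2,
    "cd27_naive_cd4",   80.5,    8.5,   83.6,    9.3,   78.4,   10.4,   80.7,    5.7,   74.8,   11.3,
    "cd28_naive_cd8",   40.8,   20.5,   56.7,   18.7,   36.7,   18.7,   49.6,   18.4,   51.4,   18.1,
    "cd27_naive_cd8",   53.7,   18.1,   74.5,   16.8,   54.5,   16.2,   67.8,   14.2,   76.8,   12.7,
    "cm_cd4",           19.7,    8.3,   21.1,    8.7,   17.7,   11.2,   22.6,    8.4,   22.7,    8.0,
    "cm_cd8",           22.9,   12.5,   11.8,    5.7,   20.9,    4.0,   16.9,    6.1,   13.0,    5.2,
    "cd38_mfi",       1402.0,  790.9,  551.8,  230.5,  658.6,  390.8,  830.6,  355.9,  526.9,  278.2,
    "il7",               4.1,    3.7,    5.4,    4.4,    4.0,    3.6,    4.9,    3.4,    2.4,    1.9,
    "log10_vl",          5.9,    0.8,    3.1,    0.6,    5.0,    1.6,    3.0,    1.0,    1.3,   0.05
  )

  long <- cells |>
    tidyr::pivot_longer(-"variable", names_to = c("cell", ".value"),
                        names_sep = "_") |>
    dplyr::mutate(
      group = dplyr::case_match(.data$cell,
        c("ad1", "ad2") ~ "ART-Def",
        c("ae1", "ae2") ~ "ART-Early",
        "heu" ~ "HEU"),
      visit = ifelse(grepl("2$", .data$cell), 2L, 1L),
      mean = .data$m, sd = .data$s
    ) |>
    dplyr::select("variable", "group", "visit", "mean", "sd")

  out <- dplyr::left_join(meta, long, by = "variable") |>
    dplyr::mutate(
      censor_lower = ifelse(.data$variable == "il7", 0.25, NA_real_),
      censor_upper = ifelse(.data$variable == "il7", 16, NA_real_)
    ) |>
    dplyr::relocate("censor_lower", "censor_upper", .after = "upper")

  if (!is.null(arm_effect)) {
    ml_assert(is.numeric(arm_effect) && !is.null(names(arm_effect)) &&
                all(names(arm_effect) %in% meta$variable),
              "`arm_effect` must be a named numeric vector of variable names")
    shift <- tibble::tibble(variable = names(arm_effect), delta = unname(arm_effect))
    out <- out |>
      dplyr::left_join(shift, by = "variable") |>
      dplyr::mutate(mean = .data$mean +
                      ifelse(.data$group == "ART-Early" & .data$visit == 2L &
                               !is.na(.data$delta), .data$delta, 0)) |>
      dplyr::select(-"delta")
  }

  validate_variable_specs(out)
  out
}

validate_variable_specs <- function(specs) {
  ml_assert(all(specs$sd > 0), "every VariableSpec SD must be > 0")
  ml_assert(all(specs$lower < specs$upper), "variable bounds must be ordered")
  bad <- specs$mean < specs$lower | specs$mean > specs$upper
  if (any(bad)) {
    ml_abort(paste0("infeasible spec: mean outside bounds for ",
                    paste(unique(specs$variable[bad]), collapse = ", ")),
             "infeasible_spec")
  }
  invisible(specs)
}

#' Cohort design configuration
#'
#' Encodes the study geometry the analysis assumes: arm sizes with visit-2
#' retention nested in visit 1 (24 ART-Def enrolments of whom 12 return; 42
#' ART-Early of whom 22 return; 23 single-visit HEU controls), visit-age
#' distributions per group and visit, log-normal ART-initiation-day targets
#' (ART-Early median 54 days, IQR 46-61; ART-Def median 220, IQR 171-341),
#' an optional additive arm effect at visit 2, and the exchangeable
#' correlation linking the T-cell panel variables.
#'
#' @param n_def,n_early Visit-1 / visit-2 sizes (length-2 integer vectors)
#'   for the deferred and early arms.
#' @param n_heu Number of single-visit HEU controls.
#' @param arm_effect Named numeric vector of additive visit-2 shifts for the
#'   ART-Early arm (passed on to [variable_specs()]).
#' @param rho Exchangeable latent correlation within the T-cell variable set.
#' @param seed Integer seed; every stochastic step of the generator is
#'   reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_def = c(24L, 12L), n_early = c(42L, 22L),
                          n_heu = 23L, arm_effect = NULL, rho = 0.3,
                          seed = 20151215L) {
  ml_assert(length(n_def) == 2 && length(n_early) == 2 &&
              all(c(n_def, n_early, n_heu) >= 0),
            "group sizes must be non-negative, visit-1 and visit-2 counts")
  ml_assert(n_def[2] <= n_def[1] && n_early[2] <= n_early[1],
            "visit-2 subjects must be a subset of visit-1 subjects")
  ml_assert(is_scalar_number(rho) && rho > -1 && rho < 1, "rho must be in (-1, 1)")

  # log-normal quantile matching: median fixes meanlog, IQR fixes sdlog
  lnorm_from_quantiles <- function(med, q25, q75) {
    ml_assert(q25 < med && med < q75, "quantile targets must be ordered")
    list(meanlog = log(med), sdlog = (log(q75) - log(q25)) / (2 * qnorm(0.75)))
  }

  structure(list(
    n = list(`ART-Def` = as.integer(n_def), `ART-Early` = as.integer(n_early),
             HEU = as.integer(c(n_heu, 0L))),
    visit_age = list( # mean, sd (days) per group/visit, truncated to >= 14 d
      `ART-Def`   = list(`1` = c(102.6, 33.9), `2` = c(263.0, 57.2)),
      `ART-Early` = list(`1` = c(118.4, 36.2), `2` = c(265.2, 71.5)),
      HEU         = list(`1` = c(129.7, 54.7))
    ),
    art_init = list(
      `ART-Early` = lnorm_from_quantiles(54, 46, 61),
      `ART-Def`   = lnorm_from_quantiles(220, 171, 341)
    ),
    arm_effect = arm_effect,
    rho = rho,
    tcell_vars = c("cd4_pct", "cd38_pct", "hladr_pct", "cd95_pct",
                   "cd28_naive_cd4", "cd27_naive_cd4", "cd28_naive_cd8",
                   "cd27_naive_cd8", "cm_cd4", "cm_cd8"),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Missingness mechanism specification
#'
#' Missingness is injected at the assay-panel level by default: a failed or
#' insufficient specimen removes every variable of that panel for that visit,
#' which is how missingness arises in specimen-constrained infant cohorts.
#' Default MCAR rates follow the observed per-assay pattern: CD4% never
#' missing (priority assay), ELISA 20% of recorded visits, flow cytometry 31%,
#' viral load 45%.
#'
#' Mechanisms: `"MCAR"` masks each panel-visit independently at its rate;
#' `"MAR"` masks with probability `plogis(a + slope * driver)` where `driver`
#' is a fully observed column and the intercept `a` is calibrated so the
#' marginal rate matches the target; `"MNAR"` uses the (standardised) value of
#' the panel's own anchor variable -- or, with `level = "cell"`, each
#' variable's own value -- as the driver.
#'
#' @param mechanism One of `"MCAR"`, `"MAR"`, `"MNAR"`.
#' @param rates Named per-panel target rates in `[0, 1)`. The `cd4` and
#'   `clinical` panels must stay at 0.
#' @param mar_driver Fully observed driver column for MAR (default
#'   `"age_days"`).
#' @param slope Logistic slope on the standardised driver (MAR) or on the
#'   variable's own standardised value (MNAR).
#' @param level `"panel"` (default: whole-panel toggle) or `"cell"`.
#' @return A list of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             rates = c(cd4 = 0, clinical = 0, elisa = 0.20,
                                       flow = 0.31, vl = 0.45),
                             mar_driver = "age_days", slope = 1,
                             level = c("panel", "cell")) {
  mechanism <- match.arg(mechanism)
  level <- match.arg(level)
  ml_assert(all(rates >= 0 & rates < 1), "panel rates must lie in [0, 1)")
  for (p in c("cd4", "clinical")) {
    if (!is.na(rates[p]) && rates[p] > 0)
      ml_abort(paste0("panel '", p, "' is never masked (priority assay)"),
               "validation")
  }
  structure(list(mechanism = mechanism, rates = rates,
                 mar_driver = mar_driver, slope = slope, level = level),
            class = "missingness_spec")
}
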