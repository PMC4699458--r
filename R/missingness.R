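#' @importFrom stats pchisq
NULL

#' Per-variable and per-panel missingness map
#'
#' Summarises where data are missing: masked fraction per measurement column,
#' per assay panel, and a subject-visit x variable indicator matrix. By
#' default the map is restricted to infected subjects with data recorded at
#' both visits -- the convention under which per-assay rates such as
#' "ELISA missing for 20% of recorded visits" are quoted.
#'
#' @param table A cohort tibble.
#' @param both_visits_only Restrict to subjects appearing at both visits
#'   (default `TRUE`).
#' @return An object of class `missingness_map`: list with `rates` (tibble:
#'   variable, panel, n_missing, n_total, rate), `panel_rates`, `matrix`
#'   (logical, `TRUE` = missing), and `n_records`.
#' @export
missingness_map <- function(table, both_visits_only = TRUE) {
  if (both_visits_only) {
    both <- table |>
      dplyr::filter(.data$group != "HEU") |>
      dplyr::count(.data$subject_id) |>
      dplyr::filter(.data$n == 2L) |>
      dplyr::pull("subject_id")
    table <- dplyr::filter(table, .data$subject_id %in% both)
  }
  vars <- measurement_vars(table)
  specs <- variable_specs()
  panel_of <- specs$panel[match(vars, specs$variable)]
  m <- is.na(as.matrix(table[vars]))
  rownames(m) <- paste0(table$subject_id, "/v", table$visit)
  rates <- tibble::tibble(
    variable = vars, panel = panel_of,
    n_missing = unname(colSums(m)), n_total = nrow(m),
    rate = unname(colSums(m)) / max(nrow(m), 1L)
  )
  panel_rates <- rates |>
    dplyr::group_by(.data$panel) |>
    dplyr::summarise(rate = sum(.data$n_missing) /
                       (max(.data$n_total) * dplyr::n()), .groups = "drop")
  structure(list(rates = rates, panel_rates = panel_rates, matrix = m,
                 n_records = nrow(m)),
            class = "missingness_map")
}

#' @export
print.missingness_map <- function(x, ...) {
  cat("<missingness_map>", x$n_records, "records\n")
  print(x$panel_rates)
  invisible(x)
}

#' Little's test of the missing-completely-at-random hypothesis
#'
#' Computes the chi-square statistic
#' \deqn{d^2 = \sum_J n_J (\bar y_{J,obs} - \hat\mu_{O_J})^\top
#'   \hat\Sigma_{O_J O_J}^{-1} (\bar y_{J,obs} - \hat\mu_{O_J})}
#' where the sum runs over distinct missingness patterns \eqn{J},
#' \eqn{\bar y_{J,obs}} is the pattern's observed-variable mean and
#' \eqn{(\hat\mu, \hat\Sigma)} the EM maximum-likelihood estimate from the
#' incomplete data, referred to a chi-square with
#' \eqn{df = \sum_J p_J - p} degrees of freedom. A significant statistic is
#' evidence against MCAR; a single pattern (complete data) makes the test
#' inapplicable and is flagged.
#'
#' Fully observed variables are kept in the observed sets (they sharpen the
#' ML estimate); rows with zero observed cells are excluded; a caveat is
#' attached when any pattern holds fewer than 5 cases.
#'
#' @param data A numeric matrix/data frame with `NA`s, or a cohort tibble (its
#'   measurement columns are used).
#' @param vars Optional character vector restricting the columns tested.
#' @return Object of class `little_test`: list with `d2`, `df`, `p_value`,
#'   `n_patterns`, `inapplicable`, `small_patterns`, `params` (the `mvn_em`
#'   fit), `pattern_table`.
#' @export
#' @examples
#' x <- mvtnorm::rmvnorm(80, sigma = diag(3))
#' x[sample(80, 20), 3] <- NA
#' little_mcar_test(x)
little_mcar_test <- function(data, vars = NULL) {
  if (is.data.frame(data) && "subject_id" %in% names(data)) {
    vars <- vars %||% measurement_vars(data)
    y <- as.matrix(data[vars])
  } else {
    y <- as.matrix(data)
    if (!is.null(vars)) y <- y[, vars, drop = FALSE]
  }
  storage.mode(y) <- "double"
  y <- y[rowSums(!is.na(y)) > 0, , drop = FALSE]
  p <- ncol(y)
  n <- nrow(y)

  pat_key <- apply(is.na(y), 1, function(m) paste(as.integer(m), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  pattern_table <- tibble::tibble(
    pattern = names(pats),
    n_observed_vars = purrr::map_int(pats, ~ sum(!is.na(y[.x[1], ]))),
    n_cases = lengths(pats)
  )

  if (length(pats) < 2) {
    fit <- em_fit(y)
    return(structure(list(d2 = 0, df = 0L, p_value = 1,
                          n_patterns = length(pats), inapplicable = TRUE,
                          small_patterns = any(lengths(pats) < 5),
                          params = fit, pattern_table = pattern_table),
                     class = "little_test"))
  }

  fit <- em_fit(y)
  mu <- fit$mean
  sigma <- fit$covariance
  d2 <- 0
  df <- 0L
  for (rows in pats) {
    o <- which(!is.na(y[rows[1], ]))
    ybar <- colMeans(y[rows, o, drop = FALSE])
    dev <- ybar - mu[o]
    s_oo <- sigma[o, o, drop = FALSE]
    q <- tryCatch(sum(dev * solve(s_oo, dev)),
                  error = function(e) sum(dev * (pseudo_inverse(s_oo) %*% dev)))
    d2 <- d2 + length(rows) * q
    df <- df + length(o)
  }
  df <- df - p
  structure(list(
    d2 = d2, df = as.integer(df),
    p_value = if (df > 0) pchisq(d2, df, lower.tail = FALSE) else 1,
    n_patterns = length(pats), inapplicable = df <= 0,
    small_patterns = any(lengths(pats) < 5),
    params = fit, pattern_table = pattern_table
  ), class = "little_test")
}

#' @export
print.little_test <- function(x, ...) {
  cat("Little's MCAR test: d2 =", format(x$d2, digits = 5),
      " df =", x$df, " p =", format(x$p_value, digits = 4), "\n")
  if (x$inapplicable) cat("  (inapplicable: fewer than two missingness patterns)\n")
  if (x$small_patterns) cat("  caveat: some patterns have fewer than 5 cases\n")
  invisible(x)
}
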