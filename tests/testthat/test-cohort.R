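test_that("generated cohort has the reference geometry with nested retention", {
  coh <- reference_cohort(seed = 11, missingness = FALSE)
  counts <- dplyr::count(coh, group, visit)
  expect_equal(counts$n, c(24, 12, 42, 22, 23))
  # every visit-2 record belongs to a subject seen at visit 1
  v1 <- coh$subject_id[coh$visit == 1]
  v2 <- coh$subject_id[coh$visit == 2]
  expect_true(all(v2 %in% v1))
  expect_false(anyNA(coh[measurement_vars(coh)]))
  expect_false(anyDuplicated(coh[c("subject_id", "visit")]) > 0)
})

test_that("same seed reproduces the identical table", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_config(seed = 6))))
})

test_that("sampled moments hit the calibration targets", {
  coh <- generate_cohort(cohort_config(seed = 21))
  s <- dplyr::filter(coh, group == "ART-Def", visit == 1)
  # 3-standard-error band around the target mean at the design n
  expect_lt(abs(mean(s$cd4_pct) - 32.9), 3 * 7.9 / sqrt(24))

  # large-n calibration: mean and SD within 2% relative error, including a
  # variable whose lower bound sits less than one SD from its mean
  big <- cohort_config(n_def = c(0L, 0L), n_early = c(4000L, 0L), n_heu = 0L,
                       seed = 22)
  cc <- generate_cohort(big)
  for (v in c("cd4_pct", "hladr_pct", "cd38_mfi", "nk_immature")) {
    target <- dplyr::filter(variable_specs(), variable == v,
                            group == "ART-Early", visit == 1)
    expect_lt(abs(mean(cc[[v]]) - target$mean) / target$mean, 0.02)
    expect_lt(abs(sd(cc[[v]]) - target$sd) / target$sd, 0.02)
  }
})

test_that("all values respect their declared bounds", {
  cc <- generate_cohort(cohort_config(n_def = c(3000L, 0L),
                                      n_early = c(3000L, 0L), seed = 31))
  specs <- variable_specs()
  for (v in unique(specs$variable)) {
    b <- specs[specs$variable == v, ][1, ]
    expect_true(all(cc[[v]] >= b$lower & cc[[v]] <= b$upper), label = v)
  }
  # percent variables never reach the exact bounds; IL-7 respects its
  # detection range
  pct <- specs$variable[specs$scale == "percent"]
  for (v in unique(pct)) {
    expect_true(all(cc[[v]] > 0 & cc[[v]] < 100), label = v)
  }
  expect_true(all(cc$il7 >= 0.25 & cc$il7 <= 16))
})

test_that("degenerate spread collapses values onto the mean", {
  specs <- variable_specs()
  specs$sd[specs$variable == "cd4_pct"] <- 1e-9
  cc <- generate_cohort(cohort_config(seed = 41), specs = specs)
  ref <- dplyr::filter(specs, variable == "cd4_pct", group == "ART-Def",
                       visit == 1)
  v <- cc$cd4_pct[cc$group == "ART-Def" & cc$visit == 1]
  expect_true(all(abs(v - ref$mean) < 1e-6))
})

test_that("infeasible specs are rejected naming the variable", {
  specs <- variable_specs()
  specs$mean[specs$variable == "cd4_pct" & specs$group == "HEU"] <- 150
  expect_error(generate_cohort(cohort_config(seed = 1), specs = specs),
               "cd4_pct", class = "misslong_infeasible_spec")
})

test_that("MCAR masking hits its target rate and leaves values unchanged", {
  cc <- generate_cohort(cohort_config(n_def = c(1000L, 0L),
                                      n_early = c(0L, 0L), n_heu = 0L,
                                      seed = 51))
  spec <- missingness_spec(rates = c(flow = 0.31))
  masked <- inject_missingness(cc, spec, seed = 52)
  frac <- mean(is.na(masked$hladr_pct))
  expect_lt(abs(frac - 0.31), 3 * sqrt(0.31 * 0.69 / 1000))
  # panel toggle: flow variables vanish together
  expect_identical(is.na(masked$hladr_pct), is.na(masked$cd38_mfi))
  # observed cells are untouched; CD4 panel never masked
  keep <- !is.na(masked$hladr_pct)
  expect_identical(masked$hladr_pct[keep], cc$hladr_pct[keep])
  expect_false(anyNA(masked$cd4_pct))

  # rate 0 leaves the table unchanged
  same <- inject_missingness(cc, missingness_spec(rates = c(flow = 0)),
                             seed = 53)
  expect_identical(same$hladr_pct, cc$hladr_pct)
})

test_that("masking mechanisms honour their selection contracts", {
  cc <- generate_cohort(cohort_config(n_def = c(5000L, 0L),
                                      n_early = c(0L, 0L), n_heu = 0L,
                                      seed = 61))
  # under MCAR, masked and observed values are exchangeable
  mcar <- inject_missingness(cc, missingness_spec(rates = c(flow = 0.3)),
                             seed = 62)
  msk <- is.na(mcar$cd95_pct)
  pooled_se <- sqrt(var(cc$cd95_pct[msk]) / sum(msk) +
                      var(cc$cd95_pct[!msk]) / sum(!msk))
  expect_lt(abs(mean(cc$cd95_pct[msk]) - mean(cc$cd95_pct[!msk])),
            3 * pooled_se)

  # under MNAR with a positive self-slope, high values are masked
  mnar <- inject_missingness(
    cc, missingness_spec("MNAR", rates = c(flow = 0.3), slope = 2,
                         level = "cell"), seed = 63)
  msk <- is.na(mnar$cd95_pct)
  expect_gt(mean(cc$cd95_pct[msk]), mean(cc$cd95_pct[!msk]))

  # a maskable MAR driver is rejected
  holey <- mcar
  expect_error(
    inject_missingness(holey, missingness_spec("MAR", rates = c(flow = 0.3),
                                               mar_driver = "cd95_pct")),
    class = "misslong_validation")
  # the priority assay cannot be given a positive rate
  expect_error(missingness_spec(rates = c(cd4 = 0.1)),
               class = "misslong_validation")
})

test_that("reference fixture matches the published availability counts", {
  coh <- reference_cohort()
  infected_v1 <- dplyr::filter(coh, visit == 1, group != "HEU")
  expect_equal(nrow(infected_v1), 66)
  both <- dplyr::count(dplyr::filter(coh, group != "HEU"), subject_id)
  expect_equal(sum(both$n == 2), 34)
  expect_equal(sum(is.na(coh$cd4_pct)), 0)
  expect_identical(reference_cohort(), coh) # packaged fixture is deterministic
})

test_that("cohort CSV round-trips and malformed input is rejected", {
  coh <- reference_cohort(seed = 71)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh, ignore_attr = TRUE)

  bad <- dplyr::rename(coh, mystery = cd4_pct)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2, na = "")
  expect_error(read_cohort(path2), "unknown columns", class = "misslong_io")

  oob <- coh
  oob$cd4_pct[1] <- 140
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(oob, path3, na = "")
  expect_error(read_cohort(path3), "out of bounds", class = "misslong_io")

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_cohort(empty), class = "misslong_io")
})

test_that("ART-initiation days match the printed quantile targets", {
  cc <- generate_cohort(cohort_config(n_def = c(2000L, 0L),
                                      n_early = c(2000L, 0L), n_heu = 0L,
                                      seed = 81))
  early <- cc$art_init_day[cc$group == "ART-Early"]
  def <- cc$art_init_day[cc$group == "ART-Def"]
  expect_lt(abs(median(early) - 54), 3)
  expect_lt(abs(median(def) - 220), 12)
  expect_lt(abs(unname(quantile(early, 0.25)) - 46), 3)
  expect_lt(abs(unname(quantile(early, 0.75)) - 61), 3)
})
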