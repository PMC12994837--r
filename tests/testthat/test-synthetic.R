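test_that("generator is byte-identical under a fixed seed and validates config", {
  cfg <- fast_synth_config(n = 800)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$ehr, c2$ehr))
  expect_error(synthetic_config(category_probs = c(White = 0.5)), "named")
  bad <- default_category_probs(); bad["White"] <- bad["White"] + 0.1
  expect_error(synthetic_config(category_probs = bad), "sum to 1")
  expect_error(synthetic_config(practice_defects = c(none = 1, no_hispanic_option = 0.5,
                                                     no_multiselect = -0.5)),
               "\\[0, 1\\]")
})

test_that("a noiseless configuration yields zero discordance and missingness", {
  cfg <- fast_synth_config(
    n = 1500, seed = 3,
    ehr_missingness = setNames(rep(0, 7), ck_reported_categories()),
    fluidity_rate = 0,
    practice_defects = c(none = 1, no_hispanic_option = 0,
                         no_multiselect = 0),
    conflict_prob = 0, allocation_prob = 0
  )
  dat <- generate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(dat))
  expect_equal(run$rates$value[run$rates$measure == "discordance_strict"], 0)
  expect_equal(run$rates$value[run$rates$measure == "missingness"], 0)
  expect_equal(run$manifest$n_cohort, cfg$n_patients)
})

test_that("flat missingness is recovered within binomial error", {
  cfg <- fast_synth_config(
    n = 20000, seed = 19,
    ehr_missingness = setNames(rep(0.2, 7), ck_reported_categories())
  )
  dat <- generate_cohort(cfg)
  masked <- mean(dat$truth$ehr_masked)
  se <- sqrt(0.2 * 0.8 / cfg$n_patients)
  expect_lt(abs(masked - 0.2), 3 * se)
})

test_that("a universal no-multiselect defect turns latent multiracial patients partial", {
  cfg <- fast_synth_config(
    n = 20000, seed = 29,
    category_probs = c(Hispanic = 0.1, White = 0.7, Black = 0.08,
                       AIAN = 0.01, Asian = 0.01, NHPI = 0.0,
                       Multiracial = 0.1),
    ehr_missingness = setNames(rep(0, 7), ck_reported_categories()),
    practice_defects = c(none = 0, no_hispanic_option = 0,
                         no_multiselect = 1)
  )
  dat <- generate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(dat))
  rec <- run$records
  multi <- rec[rec$person_key %in%
                 dat$truth$person_key[dat$truth$latent_category ==
                                        "Multiracial"], ]
  partial_share <- mean(multi$status == "partial")
  # analytic expectation: partial unless the census label moved (fluidity),
  # up to the kernel mass that lands back on a containing multirace set
  expect_lt(abs(partial_share - (1 - cfg$fluidity_rate)), 0.03)
})

test_that("closed-form expectations of the study-scale configuration hit the published magnitudes", {
  er <- expected_rates(paper_like_config())
  expect_gte(er$discordance_strict, 0.07)
  expect_lte(er$discordance_strict, 0.09)
  expect_lte(er$discordance_partial, er$discordance_strict)
  expect_gte(er$missingness_overall, 0.18)
  expect_lte(er$missingness_overall, 0.20)
  nhpi_e11 <- er$prevalence$p[er$prevalence$labeling == "census" &
                                er$prevalence$group == "NHPI" &
                                er$prevalence$outcome_group == "E11"]
  expect_lt(abs(nhpi_e11 - 0.170), 0.01)
  expect_lt(abs(er$missingness_by_census[["White"]] - 0.177), 0.01)
  expect_lt(abs(er$missingness_by_census[["Asian"]] - 0.352), 0.01)
  expect_lt(abs(er$missingness_by_census[["NHPI"]] - 0.391), 0.013)
})

test_that("pipeline recovers generator expectations at moderate scale", {
  cfg <- fast_synth_config(n = 30000, seed = 47)
  er <- expected_rates(cfg)
  dat <- generate_cohort(cfg)
  run <- suppressWarnings(run_pipeline(dat))
  n_rep <- sum(run$records$status != "nonreporting")
  mc_se <- function(p, n) sqrt(p * (1 - p) / n)
  strict <- run$rates$value[run$rates$measure == "discordance_strict"]
  expect_lt(abs(strict - er$discordance_strict),
            3 * mc_se(er$discordance_strict, n_rep))
  miss <- run$rates$value[run$rates$measure == "missingness"]
  expect_lt(abs(miss - er$missingness_overall),
            3 * mc_se(er$missingness_overall, run$manifest$n_cohort))
  expect_lte(run$rates$value[run$rates$measure == "discordance"], strict)
})

test_that("ground truth is a separate table the pipeline never consumes", {
  dat <- generate_cohort(fast_synth_config(n = 300, seed = 9))
  expect_setequal(names(dat), c("ehr", "census", "events", "covariates",
                                "truth"))
  expect_false(any(c("latent_category", "fluid") %in%
                     unlist(lapply(dat[c("ehr", "census", "events",
                                         "covariates")], names))))
  run <- suppressWarnings(run_pipeline(dat[c("ehr", "census", "events",
                                             "covariates")]))
  expect_s3_class(run, "ck_run")
})
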