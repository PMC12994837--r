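test_that("two-proportion test matches the closed-form oracle to 1e-10", {
  set.seed(17)
  for (i in 1:60) {
    n1 <- sample(5:2000, 1); n2 <- sample(5:2000, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    a <- runif(1, 0.001, 0.2)
    got <- two_proportion_test(k1, n1, k2, n2, alpha = a)
    want <- oracle_two_prop(k1, n1, k2, n2, a)
    expect_equal(got$diff_pp / 100, want[["diff"]], tolerance = 1e-10)
    expect_equal(got$lower_pp / 100, want[["lower"]], tolerance = 1e-10)
    expect_equal(got$upper_pp / 100, want[["upper"]], tolerance = 1e-10)
    expect_equal(got$p_value, want[["p_value"]], tolerance = 1e-10)
  }
  same <- two_proportion_test(30, 100, 60, 200)
  expect_equal(same$diff_pp, 0)
  expect_error(two_proportion_test(0, 0, 1, 10), "undefined")
})

test_that("covariate banding follows the table conventions", {
  cov <- tibble::tibble(
    person_key = sprintf("c%d", 1:6),
    dob = c("2010-06-01", "1980-06-01", "1950-06-01", "2004-01-01",
            "1990-01-01", "1940-01-01"),
    sex = c("male", "female", "other", "female", "male", NA),
    svi_score = c(0, 25, 25.01, 75.5, NA, 100),
    ruca_band = c("metropolitan", "rural", NA, "small town", "micropolitan",
                  "metropolitan")
  )
  b <- band_covariates(cov, reference_date = as.Date("2021-12-31"))
  expect_equal(as.character(b$age_band),
               c("<18", "18-64", ">=65", "<18", "18-64", ">=65"))
  expect_equal(b$sex[3], "other/missing")
  expect_equal(b$svi_band,
               c("[0,25]", "[0,25]", "(25,50]", "(75,100]", "missing",
                 "(75,100]"))
  expect_equal(b$ruca_band[3], "missing")
})

test_that("group contrasts produce exactly 39 antisymmetric rows with full-group denominators", {
  set.seed(23)
  n <- 900
  profiles <- tibble::tibble(
    person_key = sprintf("p%04d", 1:n),
    age_band = sample(c("<18", "18-64", ">=65"), n, replace = TRUE),
    sex = sample(c("male", "female", "other/missing"), n, replace = TRUE,
                 prob = c(0.45, 0.53, 0.02)),
    svi_band = sample(c("[0,25]", "(25,50]", "(50,75]", "(75,100]",
                        "missing"), n, replace = TRUE),
    ruca_band = sample(c("metropolitan", "micropolitan", "small town",
                         "rural", "missing"), n, replace = TRUE)
  )
  records <- tibble::tibble(
    person_key = profiles$person_key,
    status = sample(c("concordant", "discordant", "nonreporting"),
                    n, replace = TRUE, prob = c(0.7, 0.1, 0.2))
  )
  tab <- table2_comparisons(profiles, records)
  expect_equal(nrow(tab), 39)
  expect_equal(nrow(dplyr::distinct(tab, axis, level)), 13)
  # denominators are full group totals: shares recompute from raw counts
  one <- tab[tab$level == "male" & tab$group_a == "concordant" &
               tab$group_b == "discordant", ]
  n_conc <- sum(records$status == "concordant")
  k_conc <- sum(records$status == "concordant" & profiles$sex == "male")
  expect_equal(one$share_a, k_conc / n_conc)
  # identical group compositions: no significant contrasts, diffs near 0
  prof2 <- profiles
  prof2$age_band <- rep(c("<18", "18-64", ">=65"), length.out = n)
  rec2 <- records
  rec2$status <- rep(c("concordant", "discordant", "nonreporting"),
                     each = n / 3)
  tab2 <- table2_comparisons(prof2, rec2)
  age_rows <- tab2[tab2$axis == "age", ]
  expect_true(all(abs(age_rows$diff_pp) < 1))
  expect_false(any(age_rows$significant))
})

test_that("practice regressions reproduce closed-form OLS and flag degenerate fits", {
  summaries <- tibble::tibble(
    practice_key = sprintf("PR%02d", 1:5),
    n_patients = c(10, 20, 30, 40, 50),
    discordance_rate = c(20, 40, 60, 80, 100) / 1000,
    missingness_rate = rep(0.2, 5),
    nonwhite_share = c(0.1, 0.3, 0.2, 0.5, 0.4)
  )
  fits <- suppressWarnings(practice_regressions(summaries))
  slopes <- tidy(fits)
  exact <- slopes[slopes$model == "size_discordance", ]
  expect_equal(exact$estimate, 0.002, tolerance = 1e-12)
  expect_lt(exact$p.value, 1e-10)
  # degenerate: missingness_rate is constant
  degen <- slopes[slopes$model == "discordance_missingness", ]
  expect_true(is.na(degen$estimate))
  expect_match(degen$note, "degenerate")
  # closed-form oracle on every non-degenerate model
  hetero <- slopes[slopes$model == "heterogeneity_discordance", ]
  expect_equal(hetero$estimate,
               oracle_ols_slope(summaries$nonwhite_share,
                                summaries$discordance_rate),
               tolerance = 1e-10)
  expect_error(practice_regressions(summaries[1:2, ]), "at least 3")
})

test_that("uncorrelated practice noise yields null slopes at the nominal rate", {
  set.seed(37)
  pvals <- replicate(200, {
    s <- tibble::tibble(practice_key = sprintf("x%d", 1:40),
                        n_patients = sample(50:500, 40),
                        discordance_rate = runif(40, 0, 0.2),
                        missingness_rate = runif(40, 0, 0.4),
                        nonwhite_share = runif(40))
    tidy(practice_regressions(s, c(m = "discordance_rate ~ n_patients")))$p.value
  })
  # p-values approximately uniform: rejection rate near 5%
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("concentration shares are exact, monotone in top_n, and screen large practices", {
  members <- tibble::tibble(practice_key = c(rep("A", 6), rep("B", 3),
                                             rep("C", 1)))
  rep_all <- concentration_report(members, top_n = 1)
  expect_equal(rep_all$top_share, 0.6)
  shares <- vapply(1:3, function(k) {
    concentration_report(members, top_n = k)$top_share
  }, numeric(1))
  expect_true(all(diff(shares) >= 0))
  expect_equal(shares[3], 1)
  one_practice <- concentration_report(
    tibble::tibble(practice_key = rep("Z", 9)), top_n = 1)
  expect_equal(one_practice$top_share, 1)
  # uniform spread over m practices: top-n share = n/m
  unif <- tibble::tibble(practice_key = rep(sprintf("u%d", 1:10), each = 4))
  expect_equal(concentration_report(unif, top_n = 3)$top_share, 3 / 10)
  # pre-tallied input and zero-record screen
  tallied <- tibble::tibble(practice_key = c("A", "B"), n = c(38570, 97240))
  expect_equal(concentration_report(tallied, top_n = 1)$top_share,
               97240 / 135810)
  scr <- concentration_report(
    members,
    practice_sizes = tibble::tibble(practice_key = c("A", "B", "C"),
                                    n_patients = c(2000, 500, 1500)),
    screen_counts = tibble::tibble(practice_key = "A", n = 5))
  expect_equal(scr$zero_screen_practices$practice_key, "C")
  expect_equal(scr$zero_screen_share, 0.1)
})
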