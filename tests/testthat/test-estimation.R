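test_that("Wilson CC interval matches the score-inversion oracle and boundary rules", {
  expect_equal(wilson_ci(0, 10, 0.05)$lower, 0)
  expect_equal(wilson_ci(10, 10, 0.05)$upper, 1)
  ci5 <- wilson_ci(5, 10, 0.05)
  expect_equal(ci5$lower + ci5$upper, 1, tolerance = 1e-9)  # symmetry at 1/2
  ci <- wilson_ci(81, 263, 0.05)
  orc <- oracle_wilson(81, 263, 0.05)
  expect_equal(ci$lower, orc[["lower"]], tolerance = 1e-10)
  expect_equal(ci$upper, orc[["upper"]], tolerance = 1e-10)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:500, 1)
    k <- sample(0:n, 1)
    a <- runif(1, 0.001, 0.2)
    got <- wilson_ci(k, n, a)
    want <- oracle_wilson(k, n, a)
    expect_equal(got$lower, want[["lower"]], tolerance = 1e-9)
    expect_equal(got$upper, want[["upper"]], tolerance = 1e-9)
  }
  expect_error(wilson_ci(1, 0), "denominator")
  expect_error(wilson_ci(5, 3), "k")
})

test_that("Bonferroni level scales the family rate and widens intervals monotonically", {
  expect_equal(bonferroni_level(0.05, 350), 0.05 / 350)
  expect_equal(bonferroni_level(0.05, 1), 0.05)
  expect_equal(bonferroni_level(0.05, 39), 0.05 / 39)
  widths <- vapply(c(1, 10, 39, 350), function(m) {
    ci <- wilson_ci(40, 200, bonferroni_level(0.05, m))
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("group prevalence equals a hand tally with adjusted Wilson intervals", {
  set.seed(12)
  labels <- tibble::tibble(person_key = sprintf("p%03d", 1:50),
                           category = sample(c("White", "NHPI", "Unreported"),
                                             50, replace = TRUE))
  mat <- tibble::tibble(person_key = labels$person_key,
                        E11 = rbinom(50, 1, 0.3))
  pv <- group_prevalence(labels, mat, "ehr", alpha_family = 0.05,
                         n_comparisons = 10)
  for (g in c("White", "NHPI")) {
    members <- labels$person_key[labels$category == g]
    k <- sum(mat$E11[mat$person_key %in% members])
    row <- pv[pv$group == g, ]
    expect_equal(row$n, length(members))
    expect_equal(row$k, k)
    expect_equal(row$p, k / length(members))
    ci <- wilson_ci(k, length(members), 0.05 / 10)
    expect_equal(row$lower, ci$lower)
    expect_equal(row$upper, ci$upper)
  }
  expect_false("Unreported" %in% pv$group)
  # all-positive group pins the upper bound at 1
  all_pos <- group_prevalence(
    tibble::tibble(person_key = c("a", "b"), category = "Asian"),
    tibble::tibble(person_key = c("a", "b"), E11 = c(1L, 1L)), "census")
  expect_equal(all_pos$p, 1)
  expect_equal(all_pos$upper, 1)
})

test_that("prevalence shift point estimate is the difference of group proportions", {
  set.seed(21)
  n <- 400
  persons <- sprintf("p%04d", 1:n)
  le <- tibble::tibble(person_key = persons[1:350], category = "White")
  lc <- tibble::tibble(person_key = persons[51:400], category = "White")
  mat <- tibble::tibble(person_key = persons, E11 = rbinom(n, 1, 0.2))
  sh <- prevalence_shift(le, lc, mat, groups = "White", outcomes = "E11",
                         n_comparisons = 1)
  p_e <- mean(mat$E11[mat$person_key %in% le$person_key])
  p_c <- mean(mat$E11[mat$person_key %in% lc$person_key])
  expect_equal(sh$delta_pp / 100, p_c - p_e, tolerance = 1e-12)
  expect_equal(sh$p_ehr, p_e, tolerance = 1e-10)
  expect_equal(sh$p_census, p_c, tolerance = 1e-10)
  expect_equal(sh$n_overlap, 300)
  # identical labelings: zero shift, interval contains 0
  sh0 <- prevalence_shift(le, le, mat, groups = "White", outcomes = "E11")
  expect_equal(sh0$delta_pp, 0)
  expect_lte(sh0$lower_pp, 0)
  expect_gte(sh0$upper_pp, 0)
})

test_that("delta-method shift interval tracks the cluster bootstrap oracle", {
  set.seed(61)
  agree <- 0
  n_scen <- 12
  for (s in 1:n_scen) {
    n <- 500
    persons <- sprintf("p%04d", 1:n)
    both <- runif(1, 0.5, 0.9)
    in_e <- runif(n) < both | runif(n) < 0.5
    in_c <- runif(n) < both | runif(n) < 0.5
    in_e[!in_e & !in_c] <- TRUE
    y <- rbinom(n, 1, runif(1, 0.08, 0.3))
    le <- tibble::tibble(person_key = persons[in_e], category = "White")
    lc <- tibble::tibble(person_key = persons[in_c], category = "White")
    mat <- tibble::tibble(person_key = persons, E11 = y)
    sh <- prevalence_shift(le, lc, mat, groups = "White", outcomes = "E11",
                           n_comparisons = 1)
    stacked <- dplyr::bind_rows(
      tibble::tibble(person_key = persons[in_e], src = 0, y = y[in_e]),
      tibble::tibble(person_key = persons[in_c], src = 1, y = y[in_c])
    )
    boot <- oracle_boot_shift_ci(stacked, B = 500, alpha = 0.05)
    delta_covers <- sh$lower_pp <= 0 && sh$upper_pp >= 0
    boot_covers <- boot[1] <= 0 && boot[2] >= 0
    agree <- agree + (delta_covers == boot_covers)
  }
  expect_gte(agree / n_scen, 0.9)
})

test_that("pattern disaggregation partitions each aggregate exactly", {
  rec <- classify_concordance(tiny_records())
  set.seed(8)
  mat <- tibble::tibble(person_key = rec$person_key,
                        E11 = rbinom(nrow(rec), 1, 0.5))
  focus <- tibble::tibble(labeling = c("census", "ehr"),
                          group = c("White", "Black"))
  pats <- disaggregate_patterns(rec, mat, "E11", focus)
  for (i in seq_len(nrow(focus))) {
    rows <- pats[pats$labeling == focus$labeling[i] &
                   pats$group == focus$group[i], ]
    agg <- rows[rows$counterpart == "(all)", ]
    parts <- rows[rows$counterpart != "(all)", ]
    expect_equal(sum(parts$n), agg$n)
    expect_equal(sum(parts$k), agg$k)
    # aggregate prevalence is the count-weighted mean of the parts
    expect_equal(agg$p, sum(parts$p * parts$n) / sum(parts$n),
                 tolerance = 1e-12)
  }
  # single-pattern aggregate collapses to the aggregate itself
  solo <- disaggregate_patterns(
    classify_concordance(rec_row("Asian", "Asian") |>
                           dplyr::mutate(person_key = "z1", .before = 1)),
    tibble::tibble(person_key = "z1", E11 = 1L), "E11",
    tibble::tibble(labeling = "census", group = "Asian"))
  expect_equal(solo$n, c(1, 1))
  expect_equal(solo$p, c(1, 1))
  expect_error(disaggregate_patterns(rec, mat, "E11", focus[0, ]), "focus")
})
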