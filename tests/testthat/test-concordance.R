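test_that("classification matches a brute-force set-membership oracle on all single x multi-race pairs", {
  sets <- all_multirace_sets()
  grid <- tidyr::expand_grid(ehr = ck_single_races(), set = sets)
  d <- rec_row(grid$ehr, "Multiracial", census_set = grid$set)
  with_p <- classify_concordance(d, allow_partial = TRUE)
  without_p <- classify_concordance(d, allow_partial = FALSE)
  oracle <- mapply(function(r, s) r %in% strsplit(s, ";")[[1]],
                   grid$ehr, grid$set, USE.NAMES = FALSE)
  expect_equal(as.character(with_p$status),
               ifelse(oracle, "partial", "discordant"))
  expect_true(all(without_p$status == "discordant"))
})

test_that("classification handles equality, nonreporting, Hispanic, and the mirror switch", {
  d <- dplyr::bind_rows(
    rec_row("White", "White"),
    rec_row("Multiracial", "Multiracial", "Asian;White", "Black;White"),
    rec_row("Unreported", "NHPI"),
    rec_row("White", "Hispanic"),
    rec_row("Multiracial", "White", ehr_set = "Black;White")
  )
  st <- classify_concordance(d)$status
  expect_equal(as.character(st),
               c("concordant", "concordant", "nonreporting", "discordant",
                 "discordant"))
  mirrored <- classify_concordance(d, mirror_partial = TRUE)$status
  expect_equal(as.character(mirrored[5]), "partial")
  # every reported category is self-concordant
  self <- rec_row(ck_reported_categories(), ck_reported_categories())
  expect_true(all(classify_concordance(self)$status == "concordant"))
  expect_error(classify_concordance(rec_row("White", "Unreported")),
               "census label")
})

test_that("cross-tab equals a hand tally and is order-invariant", {
  rec <- classify_concordance(tiny_records())
  xt <- build_crosstab(rec)
  expect_equal(xt$n, 10)
  expect_equal(xt$counts["White", "White"], 2)
  expect_equal(xt$counts["Black", "Multiracial"], 2)
  expect_equal(xt$counts["Unreported", "White"], 1)
  expect_equal(sum(xt$counts), nrow(rec))
  # row percentages sum to 100 over nonempty rows
  nonzero <- rowSums(xt$counts) > 0
  expect_equal(unname(rowSums(xt$row_pct)[nonzero]),
               rep(100, sum(nonzero)), tolerance = 1e-9)
  # column pct: reported rows sum to 100; Unreported row is % of full column
  expect_equal(sum(xt$col_pct[1:7, "White"]), 100)
  expect_equal(xt$col_pct["Unreported", "White"], 100 * 1 / 3)
  shuffled <- build_crosstab(rec[sample.int(nrow(rec)), ])
  expect_identical(shuffled$counts, xt$counts)
  # single record and empty input
  one <- build_crosstab(classify_concordance(rec_row("White", "White")))
  expect_equal(sum(one$counts), 1)
  expect_equal(one$row_pct["White", "White"], 100)
  expect_equal(sum(build_crosstab(rec[0, ])$counts), 0)
})

test_that("discordance and missingness rates equal direct tallies", {
  rec <- classify_concordance(tiny_records())
  st <- as.character(rec$status)
  reporting <- sum(st != "nonreporting")
  expect_equal(discordance_rate(rec, allow_partial = TRUE),
               sum(st == "discordant") / reporting)
  expect_equal(discordance_rate(rec, allow_partial = FALSE),
               sum(st %in% c("discordant", "partial")) / reporting)
  expect_lte(discordance_rate(rec, TRUE), discordance_rate(rec, FALSE))
  expect_equal(missingness_rate(rec), mean(st == "nonreporting"))
  by_c <- missingness_rate(rec, by = "census")
  nhpi <- by_c[by_c$census_category == "NHPI", ]
  expect_equal(nhpi$rate, 1)  # the only NHPI person is nonreporting
  all_conc <- classify_concordance(rec_row(c("White", "Asian"),
                                           c("White", "Asian")))
  expect_equal(discordance_rate(all_conc), 0)
  expect_equal(missingness_rate(all_conc), 0)
  expect_error(discordance_rate(classify_concordance(
    rec_row("Unreported", "White"))), "undefined")
})

test_that("rates accept pre-tallied count input", {
  counts <- tibble::tibble(
    status = c("concordant", "discordant", "nonreporting"),
    n = c(90, 10, 25)
  )
  expect_equal(discordance_rate(counts, weight = "n"), 0.1)
  expect_equal(missingness_rate(counts, weight = "n"), 0.2)
})

test_that("discordant composition matches cross-tab off-diagonals and sums to 100", {
  rec <- classify_concordance(tiny_records(), allow_partial = FALSE)
  xt <- build_crosstab(rec)
  comp <- discordant_composition(rec, "ehr", allow_partial = FALSE)
  off_diag <- vapply(ck_reported_categories(), function(g) {
    sum(xt$counts[g, setdiff(ck_reported_categories(), g)])
  }, numeric(1))
  expect_equal(setNames(comp$n, as.character(comp$category)), off_diag)
  expect_equal(sum(comp$share_pct), 100, tolerance = 1e-9)
  comp_c <- discordant_composition(rec, "census", allow_partial = FALSE)
  expect_equal(sum(comp_c$share_pct), 100, tolerance = 1e-9)
  one <- discordant_composition(
    classify_concordance(rec_row("White", "Hispanic")), "census")
  expect_equal(one$share_pct[one$category == "Hispanic"], 100)
})

test_that("partial switch only affects single-race-in-census-set pairs", {
  set.seed(55)
  cats <- ck_reported_categories()
  sets <- all_multirace_sets()
  d <- tibble::tibble(
    ehr_category = sample(c(cats, "Unreported"), 400, replace = TRUE),
    ehr_race_set = "",
    census_category = sample(cats, 400, replace = TRUE),
    census_race_set = ""
  ) |>
    dplyr::mutate(census_race_set = ifelse(census_category == "Multiracial",
                                           sample(sets, 400, replace = TRUE),
                                           ""))
  a <- classify_concordance(d, allow_partial = TRUE)$status
  b <- classify_concordance(d, allow_partial = FALSE)$status
  differs <- which(a != b)
  expect_true(all(a[differs] == "partial"))
  expect_true(all(
    d$census_category[differs] == "Multiracial" &
      mapply(function(r, s) r %in% strsplit(s, ";")[[1]],
             d$ehr_category[differs], d$census_race_set[differs])
  ))
})

test_that("crosstab tidier and plot accessors work", {
  rec <- classify_concordance(tiny_records())
  xt <- build_crosstab(rec)
  td <- tidy(xt)
  expect_equal(nrow(td), 56)
  expect_equal(sum(td$count), 10)
  gl <- glance(xt)
  expect_equal(gl$missingness, missingness_rate(rec))
  p <- ggplot2::autoplot(xt)
  expect_s3_class(p, "ggplot")
})
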