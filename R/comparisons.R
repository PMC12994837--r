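#' Two-sample test for equality of proportions
#'
#' Continuity-corrected two-sample z-test (the classic chi-squared test
#' with Yates correction, as fitted by [stats::prop.test()]), reporting
#' the difference in percentage points with a confidence interval at the
#' supplied, typically Bonferroni-adjusted, level.
#'
#' @param k1,n1,k2,n2 Successes and totals for the two samples
#'   (vectorized; recycled to a common length).
#' @param alpha Two-sided level for the interval.
#' @return Tibble `p1`, `p2`, `diff_pp`, `lower_pp`, `upper_pp`,
#'   `p_value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, alpha = 0.05) {
  args <- vctrs_recycle(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(args$n1 < 1 | args$n2 < 1)) {
    abort("two_proportion_test undefined for empty samples")
  }
  purrr::pmap_dfr(args, function(k1, n1, k2, n2) {
    tst <- suppressWarnings(
      prop.test(c(k1, k2), c(n1, n2), conf.level = 1 - alpha)
    )
    tibble(p1 = k1 / n1, p2 = k2 / n2,
           diff_pp = 100 * (k1 / n1 - k2 / n2),
           lower_pp = 100 * tst$conf.int[1],
           upper_pp = 100 * tst$conf.int[2],
           p_value = tst$p.value)
  })
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

#' Band patient covariates for group comparisons
#'
#' Derives the comparison bands used in the demographic contrast table:
#' age at a reference date (`<18`, `18-64`, `>=65`), sex
#' (`male`/`female`/`other/missing`), SVI percentile quartile bands with
#' the half-open convention `[0,25]`, `(25,50]`, `(50,75]`, `(75,100]`,
#' and RUCA rurality bands. Missing SVI or RUCA yields `missing`.
#'
#' @param covariates Tibble `person_key`, `dob` (Date or yyyy-mm-dd
#'   string), `sex`, `svi_score` (0-100 or `NA`), `ruca_band` (one of
#'   metropolitan/micropolitan/small town/rural or `NA`).
#' @param reference_date Date at which age is computed (default the end
#'   of the emulated record window).
#' @return Tibble `person_key`, `age_band`, `sex`, `svi_band`,
#'   `ruca_band`.
#' @export
band_covariates <- function(covariates, reference_date = as.Date("2021-12-31")) {
  assert_cols(covariates, c("person_key", "dob", "sex", "svi_score",
                            "ruca_band"))
  age <- floor(as.numeric(reference_date - as.Date(covariates$dob)) / 365.25)
  svi <- covariates$svi_score
  ruca_levels <- c("metropolitan", "micropolitan", "small town", "rural")
  tibble(
    person_key = covariates$person_key,
    age_band = cut(age, c(-Inf, 17, 64, Inf),
                   labels = c("<18", "18-64", ">=65")),
    sex = ifelse(covariates$sex %in% c("male", "female"),
                 as.character(covariates$sex), "other/missing"),
    svi_band = ifelse(is.na(svi), "missing",
                      as.character(cut(svi, c(-0.001, 25, 50, 75, 100),
                                       labels = c("[0,25]", "(25,50]",
                                                  "(50,75]", "(75,100]")))),
    ruca_band = ifelse(is.na(covariates$ruca_band) |
                         !(covariates$ruca_band %in% ruca_levels),
                       "missing", as.character(covariates$ruca_band))
  )
}

comparison_levels <- function() {
  tibble::tribble(
    ~axis, ~level,
    "age", "<18", "age", "18-64", "age", ">=65",
    "sex", "male", "sex", "female",
    "svi", "[0,25]", "svi", "(25,50]", "svi", "(50,75]", "svi", "(75,100]",
    "ruca", "metropolitan", "ruca", "micropolitan",
    "ruca", "small town", "ruca", "rural"
  )
}

#' Pairwise demographic contrasts across concordance groups
#'
#' For each of the 13 characteristic levels (3 age bands, 2 sexes, 4 SVI
#' bands, 4 RUCA bands) and each of the 3 pairs of concordance groups
#' (concordant, discordant, nonreporting; partially concordant persons
#' are folded into the discordant group, matching the strict grouping of
#' the published contrast table), runs [two_proportion_test()] at the
#' Bonferroni-adjusted level `alpha_family / 39`. Denominators are full
#' group totals: persons with missing address information simply never
#' fall in an SVI/RUCA band, and other/missing sex never falls in a sex
#' band, so those shares need not total 100%.
#'
#' @param profiles Banded covariates from [band_covariates()].
#' @param records Classified records (`person_key`, `status`).
#' @param alpha_family Family-wise error rate (default 0.05).
#' @return Tibble of 39 rows: `axis`, `level`, `group_a`, `group_b`,
#'   shares, `diff_pp`, `lower_pp`, `upper_pp`, `p_value`,
#'   `significant`. Levels with no members anywhere are skipped with a
#'   message.
#' @export
table2_comparisons <- function(profiles, records, alpha_family = 0.05) {
  assert_cols(records, c("person_key", "status"))
  grp <- tibble::as_tibble(records) |>
    mutate(cgroup = dplyr::case_match(as.character(status),
                                      "concordant" ~ "concordant",
                                      c("discordant", "partial") ~ "discordant",
                                      "nonreporting" ~ "nonreporting")) |>
    select(person_key, cgroup)
  dat <- inner_join(profiles, grp, by = "person_key")
  groups <- c("concordant", "discordant", "nonreporting")
  if (any(!groups %in% dat$cgroup)) abort("all three concordance groups must be nonempty")
  totals <- dat |> count(cgroup, name = "n_total")
  alpha <- bonferroni_level(alpha_family, 39L)
  pairs <- tibble(group_a = c("concordant", "concordant", "discordant"),
                  group_b = c("discordant", "nonreporting", "nonreporting"))
  axis_col <- c(age = "age_band", sex = "sex", svi = "svi_band",
                ruca = "ruca_band")

  purrr::pmap_dfr(comparison_levels(), function(axis, level) {
    hit <- dat[as.character(dat[[axis_col[[axis]]]]) == level, , drop = FALSE]
    if (nrow(hit) == 0L) {
      message("no persons at level ", level, "; skipped")
      return(NULL)
    }
    ks <- hit |> count(cgroup, name = "k") |>
      right_join(totals, by = "cgroup") |>
      mutate(k = tidyr::replace_na(k, 0L))
    lut_k <- setNames(ks$k, ks$cgroup)
    lut_n <- setNames(ks$n_total, ks$cgroup)
    purrr::pmap_dfr(pairs, function(group_a, group_b) {
      tst <- two_proportion_test(lut_k[[group_a]], lut_n[[group_a]],
                                 lut_k[[group_b]], lut_n[[group_b]],
                                 alpha = alpha)
      tibble(axis = axis, level = level, group_a = group_a,
             group_b = group_b,
             share_a = tst$p1, share_b = tst$p2,
             diff_pp = tst$diff_pp, lower_pp = tst$lower_pp,
             upper_pp = tst$upper_pp, p_value = tst$p_value,
             significant = tst$p_value < alpha)
    })
  })
}

#' Summarize classified records at the practice level
#'
#' @param records Classified records with `person_key`, `status`,
#'   `census_category`.
#' @param practices Tibble `person_key`, `practice_key`; may be omitted
#'   when `records` already carries a `practice_key` column.
#' @return Tibble `practice_key`, `n_patients`, `discordance_rate`
#'   (strict, among reporting patients; `NA` if none report),
#'   `missingness_rate`, `nonwhite_share` (census-labeled).
#' @export
practice_summaries <- function(records, practices = NULL) {
  assert_cols(records, c("person_key", "status", "census_category"))
  records <- tibble::as_tibble(records)
  if (!is.null(practices)) {
    assert_cols(practices, c("person_key", "practice_key"))
    records <- inner_join(records[, setdiff(names(records), "practice_key")],
                          tibble::as_tibble(practices), by = "person_key")
  }
  assert_cols(records, "practice_key")
  records |>
    group_by(practice_key) |>
    summarise(
      n_patients = n(),
      discordance_rate = {
        rep_n <- sum(status != "nonreporting")
        if (rep_n == 0) NA_real_ else
          sum(status %in% c("discordant", "partial")) / rep_n
      },
      missingness_rate = mean(status == "nonreporting"),
      nonwhite_share = mean(as.character(census_category) != "White"),
      .groups = "drop"
    )
}

default_practice_models <- function() {
  c(size_discordance = "discordance_rate ~ n_patients",
    size_missingness = "missingness_rate ~ n_patients",
    discordance_missingness = "discordance_rate ~ missingness_rate",
    heterogeneity_discordance = "discordance_rate ~ nonwhite_share",
    heterogeneity_missingness = "missingness_rate ~ nonwhite_share")
}

#' Practice-level simple linear regressions
#'
#' Ordinary least-squares fits of practice-level rates on practice
#' attributes. The default model set covers the five relationships of
#' interest: discordance and missingness rate against practice size,
#' discordance against missingness, and both rates against the
#' practice's non-White patient share (population heterogeneity).
#'
#' @param summaries Practice summaries from [practice_summaries()]
#'   (at least 3 practices).
#' @param models Named character vector of formulas.
#' @return Object of class `ck_practice_fits`: a list of `lm` fits plus
#'   a tidy slope table (`model`, `term`, `estimate`, `std.error`,
#'   `p.value`, `note`); a constant regressor degrades only its own
#'   model (`NA` estimates, noted).
#' @export
practice_regressions <- function(summaries, models = default_practice_models()) {
  if (nrow(summaries) < 3L) abort("at least 3 practices are required")
  fits <- list()
  rows <- purrr::imap_dfr(models, function(f, nm) {
    fml <- as.formula(f)
    xvar <- all.vars(fml)[2]
    dat <- summaries[stats::complete.cases(summaries[, all.vars(fml)]), ]
    if (length(unique(dat[[xvar]])) < 2L) {
      return(tibble(model = nm, term = xvar, estimate = NA_real_,
                    std.error = NA_real_, p.value = NA_real_,
                    note = "degenerate fit: constant regressor"))
    }
    fit <- lm(fml, data = dat)
    fits[[nm]] <<- fit
    sm <- summary(fit)$coefficients
    tibble(model = nm, term = xvar, estimate = sm[2, 1],
           std.error = sm[2, 2], p.value = sm[2, 4], note = NA_character_)
  })
  structure(list(fits = fits, slopes = rows), class = "ck_practice_fits")
}

#' @export
print.ck_practice_fits <- function(x, ...) {
  cat("Practice-level OLS fits\n")
  print(x$slopes)
  invisible(x)
}

#' Concentration of a discordance pattern across practices
#'
#' Ranks practices by the number of members of a discordance pattern
#' (e.g. EHR non-Hispanic but census Hispanic) they contribute, and
#' reports the share of all members accounted for by the top practices.
#' Optionally screens for large practices with zero records of a given
#' kind (e.g. large practices with no Multiracial EHR records), and the
#' share of pattern members attending them.
#'
#' @param members Tibble with a `practice_key` column, one row per
#'   pattern member, or a pre-tallied tibble `practice_key`, `n`.
#' @param top_n Number of top practices (default 10).
#' @param practice_sizes Optional tibble `practice_key`, `n_patients`
#'   for the zero-record screen.
#' @param screen_counts Optional tibble `practice_key`, `n` counting the
#'   screened record type per practice (practices absent count as zero).
#' @param size_threshold Minimum `n_patients` for a "large" practice
#'   (default 1000, exclusive).
#' @return List: `n_members`, `top_n`, `top_share` (proportion),
#'   `top_practices` tibble, and -- when the screen inputs are given --
#'   `zero_screen_practices` and `zero_screen_share`.
#' @export
concentration_report <- function(members, top_n = 10L,
                                 practice_sizes = NULL,
                                 screen_counts = NULL,
                                 size_threshold = 1000L) {
  assert_cols(members, "practice_key")
  counts <- if ("n" %in% names(members)) {
    tibble::as_tibble(members)[, c("practice_key", "n")]
  } else {
    count(tibble::as_tibble(members), practice_key, name = "n")
  }
  if (sum(counts$n) == 0) abort("pattern has no members")
  counts <- arrange(counts, desc(n), practice_key)
  total <- sum(counts$n)
  top <- head(counts, top_n)
  out <- list(n_members = total, top_n = top_n,
              top_share = sum(top$n) / total, top_practices = top)
  if (!is.null(practice_sizes) && !is.null(screen_counts)) {
    screen <- practice_sizes |>
      left_join(screen_counts, by = "practice_key") |>
      mutate(n = tidyr::replace_na(n, 0L)) |>
      filter(n_patients > size_threshold, n == 0L)
    out$zero_screen_practices <- screen
    out$zero_screen_share <-
      sum(counts$n[counts$practice_key %in% screen$practice_key]) / total
  }
  out
}
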