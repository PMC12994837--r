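#' Run the full concordance analysis pipeline
#'
#' Executes the stages in dependency order: EHR harmonization, census
#' resolution, concordance classification, outcome ever-indicators,
#' prevalence and shift estimation, demographic and practice-level
#' comparisons, and (optionally) disclosure-style count protection of
#' the cross-tab. The linked cohort is the set of persons with a
#' resolved census label, matching the design of the analyses this
#' package emulates. Rerunning with the same inputs and configuration
#' reproduces identical outputs.
#'
#' @param data List of input tibbles `ehr`, `census`, `events`,
#'   `covariates` (the schemas emitted by [generate_cohort()]).
#' @param mapping EHR code mapping (see [read_ehr_mapping()]).
#' @param crosswalk Outcome crosswalk (see [read_crosswalk()]).
#' @param allow_partial Recognize partial concordance.
#' @param top_k Number of outcome groups carried into estimation.
#' @param exclude_prefixes Outcome stems excluded from the top-k ranking
#'   (default `"Z"`, encounter-reason codes).
#' @param shift_family,table2_alpha Family size for shift intervals and
#'   family-wise level for the demographic contrasts.
#' @param priority Census resolution priority switch.
#' @param focus_groups Groups disaggregated by recording pattern for the
#'   first outcome (default NHPI and White under both labelings).
#' @param protect Optional [noise_config()] applied to the released
#'   cross-tab counts.
#' @return Object of class `ck_run`: a list with elements `records`,
#'   `crosstab` (+ `crosstab_protected` when `protect` is given),
#'   `rates`, `composition`, `outcome_matrix`, `top_outcomes`,
#'   `prevalence`, `shifts`, `patterns`, `table2`, `practice`
#'   (summaries, fits, concentration), and `manifest`.
#' @export
run_pipeline <- function(data,
                         mapping = read_ehr_mapping(),
                         crosswalk = read_crosswalk(),
                         allow_partial = TRUE,
                         top_k = 8L,
                         exclude_prefixes = "Z",
                         shift_family = 350L,
                         table2_alpha = 0.05,
                         priority = "decennial",
                         focus_groups = NULL,
                         protect = NULL) {
  needed <- c("ehr", "census", "events", "covariates")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("pipeline aborted at stage `%s`: input table missing",
                  c(ehr = "harmonize", census = "census_resolution",
                    events = "outcomes",
                    covariates = "cohort_comparisons")[missing[1]]))
  }
  stages <- character(0)

  ehr_lab <- harmonize_ehr(data$ehr, mapping)
  stages <- c(stages, "harmonize")

  resolved <- resolve_census(data$census, priority = priority)
  cohort <- resolved |> filter(!is.na(category))
  stages <- c(stages, "resolve")

  records <- inner_join(
    ehr_lab |> select(person_key, practice_key,
                      ehr_category = category, ehr_race_set = race_set),
    cohort |> select(person_key, census_category = category,
                     census_race_set = race_set),
    by = "person_key"
  ) |>
    classify_concordance(allow_partial = allow_partial)
  stages <- c(stages, "classify")

  xtab <- build_crosstab(records)
  rates <- tibble(
    measure = c("discordance", "discordance_strict", "missingness"),
    value = c(discordance_rate(records, allow_partial = TRUE),
              discordance_rate(records, allow_partial = FALSE),
              missingness_rate(records))
  )
  composition <- if (any(records$status == "discordant")) {
    bind_rows(
      discordant_composition(records, "ehr") |> mutate(standpoint = "ehr"),
      discordant_composition(records, "census") |> mutate(standpoint = "census")
    )
  } else {
    message("no discordant records; composition table empty")
    tibble()
  }
  stages <- c(stages, "crosstab")

  omat <- ever_indicators(data$events, crosswalk,
                          persons = records$person_key)
  top <- top_k_outcomes(omat, k = min(top_k, ncol(omat) - 1L),
                        exclude_prefixes = exclude_prefixes)
  stages <- c(stages, "outcomes")

  ehr_labels <- records |>
    filter(status != "nonreporting") |>
    select(person_key, category = ehr_category)
  cen_labels <- records |> select(person_key, category = census_category)
  prevalence <- bind_rows(
    group_prevalence(cen_labels, omat, "census", outcomes = top,
                     alpha_family = 0.05, n_comparisons = shift_family),
    group_prevalence(ehr_labels, omat, "ehr", outcomes = top,
                     alpha_family = 0.05, n_comparisons = shift_family)
  )
  shifts <- prevalence_shift(ehr_labels, cen_labels, omat, outcomes = top,
                             n_comparisons = shift_family)
  focus_groups <- focus_groups %||%
    tidyr::expand_grid(labeling = c("ehr", "census"),
                       group = c("NHPI", "White"))
  patterns <- disaggregate_patterns(records, omat, top[1], focus_groups,
                                    n_comparisons = shift_family)
  stages <- c(stages, "estimate")

  profiles <- band_covariates(data$covariates)
  table2 <- if (all(c("concordant", "discordant", "nonreporting") %in%
                    as.character(records$status))) {
    table2_comparisons(profiles, records, alpha_family = table2_alpha)
  } else {
    message("not all three concordance groups present; contrasts skipped")
    tibble()
  }
  psumm <- practice_summaries(records)
  pfits <- practice_regressions(psumm)
  hisp_pattern <- records |>
    filter(as.character(ehr_category) %in%
             setdiff(ck_reported_categories(), "Hispanic"),
           as.character(census_category) == "Hispanic")
  conc <- if (nrow(hisp_pattern) > 0L) {
    concentration_report(
      hisp_pattern[, "practice_key"],
      practice_sizes = psumm[, c("practice_key", "n_patients")],
      screen_counts = records |>
        filter(as.character(ehr_category) == "Multiracial") |>
        count(practice_key, name = "n")
    )
  } else {
    message("no EHR non-Hispanic / census Hispanic pattern members")
    NULL
  }
  stages <- c(stages, "compare")

  out <- list(records = records, crosstab = xtab, rates = rates,
              composition = composition, outcome_matrix = omat,
              top_outcomes = top, prevalence = prevalence, shifts = shifts,
              patterns = patterns, table2 = table2,
              practice = list(summaries = psumm, fits = pfits,
                              concentration = conc))
  if (!is.null(protect)) {
    out$crosstab_protected <- protect_counts(xtab$counts, protect)
    stages <- c(stages, "protect")
  }
  stages <- c(stages, "manifest")
  out$manifest <- list(
    stages = stages,
    n_ehr = nrow(data$ehr),
    n_cohort = nrow(records),
    n_dropped_allocated = sum(resolved$n_dropped_allocated),
    n_dropped_conflict = sum(resolved$n_dropped_conflict),
    n_unlinked = sum(is.na(resolved$category)),
    allow_partial = allow_partial,
    top_outcomes = top,
    config_hash = rlang::hash(list(allow_partial, top_k, exclude_prefixes,
                                   shift_family, table2_alpha, priority))
  )
  class(out) <- "ck_run"
  out
}

#' @export
print.ck_run <- function(x, ...) {
  m <- x$manifest
  cat("concordkit pipeline run:", length(m$stages), "stages complete\n")
  cat("  cohort:", m$n_cohort, "linked persons (of", m$n_ehr, "EHR patients)\n")
  cat(sprintf("  discordance %.1f%% (strict %.1f%%), missingness %.1f%%\n",
              100 * x$rates$value[1], 100 * x$rates$value[2],
              100 * x$rates$value[3]))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `ck_run` object.
#' @export
glance.ck_run <- function(x, ...) {
  tibble(n_cohort = x$manifest$n_cohort,
         discordance = x$rates$value[1],
         discordance_strict = x$rates$value[2],
         missingness = x$rates$value[3],
         n_outcomes = length(x$top_outcomes))
}
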