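#' Continuity-corrected Wilson score interval
#'
#' Two-sided score interval for a binomial proportion with the Yates
#' continuity correction, clipped to `[0, 1]`; the lower bound is 0 when
#' the numerator is 0 and the upper bound is 1 at the other boundary.
#' Vectorized over `k` and `n`.
#'
#' @param k Number of successes.
#' @param n Number of trials (at least 1).
#' @param alpha Two-sided error level (use the Bonferroni-adjusted level
#'   from [bonferroni_level()] for families of intervals).
#' @return Tibble with columns `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, alpha = 0.05) {
  if (any(n < 1)) abort("wilson_ci undefined for denominator 0")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  k <- as.numeric(k); n <- as.numeric(n)
  z <- qnorm(1 - alpha / 2)
  p <- k / n
  denom <- 2 * (n + z^2)
  low_disc <- z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1)
  upp_disc <- z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1)
  lower <- (2 * n * p + z^2 - 1 - z * sqrt(pmax(low_disc, 0))) / denom
  upper <- (2 * n * p + z^2 + 1 + z * sqrt(pmax(upp_disc, 0))) / denom
  lower <- pmin(pmax(lower, 0), 1)
  upper <- pmin(pmax(upper, 0), 1)
  lower[k == 0] <- 0
  upper[k == n] <- 1
  tibble(lower = lower, upper = upper)
}

#' Per-comparison level under a Bonferroni family-wise correction
#'
#' @param alpha_family Family-wise error rate (e.g. 0.05).
#' @param n_comparisons Number of comparisons in the family.
#' @return `alpha_family / n_comparisons`.
#' @export
bonferroni_level <- function(alpha_family = 0.05, n_comparisons = 1L) {
  if (n_comparisons < 1) abort("`n_comparisons` must be at least 1")
  alpha_family / n_comparisons
}

join_labels <- function(labels, outcome_matrix) {
  assert_cols(labels, c("person_key", "category"))
  assert_cols(outcome_matrix, "person_key")
  inner_join(tibble::as_tibble(labels)[, c("person_key", "category")],
             tibble::as_tibble(outcome_matrix), by = "person_key")
}

#' Group-level outcome prevalence with adjusted Wilson intervals
#'
#' For each racial/ethnic group under one labeling source, the prevalence
#' of each outcome group is the share of that group's persons with an
#' ever-indicator of 1. Under EHR labeling, `Unreported` persons have no
#' group and are excluded; census labels are always reported. Intervals
#' are continuity-corrected Wilson intervals at the Bonferroni-adjusted
#' level `alpha_family / n_comparisons`.
#'
#' @param labels Tibble `person_key`, `category` for one labeling source.
#' @param outcome_matrix Ever-indicator matrix (see [ever_indicators()]).
#' @param labeling Tag recorded in the output: `"ehr"` or `"census"`.
#' @param outcomes Outcome groups to estimate (default: all columns).
#' @param alpha_family,n_comparisons Family-wise level and family size.
#' @return Tibble `group`, `outcome_group`, `labeling`, `n`, `k`, `p`,
#'   `lower`, `upper`. Empty groups are flagged with a message and
#'   omitted.
#' @export
group_prevalence <- function(labels, outcome_matrix,
                             labeling = c("census", "ehr"),
                             outcomes = NULL, alpha_family = 0.05,
                             n_comparisons = 1L) {
  labeling <- match.arg(labeling)
  joined <- join_labels(labels, outcome_matrix)
  joined <- joined[as.character(joined$category) != "Unreported", ,
                   drop = FALSE]
  outcomes <- outcomes %||% setdiff(names(outcome_matrix), "person_key")
  alpha <- bonferroni_level(alpha_family, n_comparisons)
  out <- joined |>
    mutate(group = factor(as.character(category),
                          levels = ck_reported_categories())) |>
    group_by(group, .drop = FALSE) |>
    summarise(across(all_of(outcomes), list(k = ~ sum(.x), n = ~ length(.x))),
              .groups = "drop") |>
    tidyr::pivot_longer(-group, names_to = c("outcome_group", ".value"),
                        names_pattern = "(.*)_([kn])$")
  empty <- unique(out$group[out$n == 0])
  if (length(empty) > 0L) {
    message("no persons labeled ", paste(empty, collapse = ", "),
            " under the ", labeling, " labeling; group(s) omitted")
    out <- out[out$n > 0, , drop = FALSE]
  }
  ci <- wilson_ci(out$k, out$n, alpha)
  out |>
    mutate(labeling = labeling, p = .data$k / .data$n,
           lower = ci$lower, upper = ci$upper) |>
    select(group, outcome_group, labeling, n, k, p, lower, upper)
}

delta_shift_fit <- function(stacked, alpha, weights = NULL) {
  # stacked: person_key, src (0 = EHR denominator, 1 = census), y
  w <- weights %||% rep(1, nrow(stacked))
  fit <- suppressWarnings(
    glm(y ~ src, family = binomial(), data = stacked, weights = w)
  )
  V <- sandwich::vcovCL(fit, cluster = stacked$person_key)
  # in the saturated intercept + indicator model the fitted group
  # probabilities are the (weighted) sample proportions; using them
  # directly avoids IRLS round-off in the point estimate
  p0 <- sum(w * stacked$y * (stacked$src == 0)) / sum(w * (stacked$src == 0))
  p1 <- sum(w * stacked$y * (stacked$src == 1)) / sum(w * (stacked$src == 1))
  # gradient of p1 - p0 wrt (b0, b1)
  g <- c(p1 * (1 - p1) - p0 * (1 - p0), p1 * (1 - p1))
  se <- sqrt(drop(t(g) %*% V %*% g))
  z <- qnorm(1 - alpha / 2)
  list(delta = p1 - p0, se = se,
       lower = p1 - p0 - z * se, upper = p1 - p0 + z * se,
       p_ehr = p0, p_census = p1)
}

#' Prevalence shift between EHR and census labelings
#'
#' For each requested group and outcome, estimates how the group's
#' prevalence changes when group membership is taken from the census
#' labeling instead of the EHR labeling (census minus EHR, in percentage
#' points). The two group denominators are stacked with a source
#' indicator and an intercept + indicator logistic model is fitted (by
#' default unweighted; a per-person weight column may be supplied); the
#' probability-difference scale interval is a Wald interval from the
#' delta method, with the variance clustered on persons appearing in both
#' denominators. Intervals use the Bonferroni-adjusted level.
#'
#' @param labels_ehr,labels_census Tibbles `person_key`, `category`.
#' @param outcome_matrix Ever-indicator matrix.
#' @param groups Groups to estimate (default: all seven reported). A
#'   group absent under one labeling is flagged and skipped.
#' @param outcomes Outcome groups (default: all matrix columns).
#' @param alpha_family,n_comparisons Family-wise level and family size
#'   (the published analysis uses 0.05 over 350 group-outcome pairs).
#' @param weights Optional tibble `person_key`, `weight`.
#' @return Tibble of class `ck_shift`: `group`, `outcome_group`,
#'   `n_ehr`, `n_census`, `n_overlap`, `p_ehr`, `p_census`, `delta_pp`,
#'   `lower_pp`, `upper_pp`.
#' @export
prevalence_shift <- function(labels_ehr, labels_census, outcome_matrix,
                             groups = NULL, outcomes = NULL,
                             alpha_family = 0.05, n_comparisons = 350L,
                             weights = NULL) {
  ehr <- join_labels(labels_ehr, outcome_matrix)
  cen <- join_labels(labels_census, outcome_matrix)
  groups <- groups %||% ck_reported_categories()
  outcomes <- outcomes %||% setdiff(names(outcome_matrix), "person_key")
  alpha <- bonferroni_level(alpha_family, n_comparisons)
  wlut <- if (!is.null(weights)) {
    setNames(weights$weight, weights$person_key)
  }

  res <- purrr::map_dfr(groups, function(g) {
    de <- ehr[as.character(ehr$category) == g, , drop = FALSE]
    dc <- cen[as.character(cen$category) == g, , drop = FALSE]
    if (nrow(de) == 0L || nrow(dc) == 0L) {
      message("group ", g, " absent under one labeling; shift skipped")
      return(NULL)
    }
    purrr::map_dfr(outcomes, function(o) {
      stacked <- bind_rows(
        tibble(person_key = de$person_key, src = 0, y = de[[o]]),
        tibble(person_key = dc$person_key, src = 1, y = dc[[o]])
      )
      w <- if (!is.null(wlut)) unname(wlut[as.character(stacked$person_key)])
      est <- delta_shift_fit(stacked, alpha, w)
      tibble(group = g, outcome_group = o,
             n_ehr = nrow(de), n_census = nrow(dc),
             n_overlap = length(intersect(de$person_key, dc$person_key)),
             p_ehr = est$p_ehr, p_census = est$p_census,
             delta_pp = 100 * est$delta,
             lower_pp = 100 * est$lower, upper_pp = 100 * est$upper)
    })
  })
  class(res) <- c("ck_shift", class(res))
  res
}

#' Disaggregate an aggregate prevalence into recording-pattern cohorts
#'
#' Each focus aggregate (a group under one labeling, e.g. census-NHPI)
#' partitions into constituent cohorts keyed by the counterpart label --
#' the person's category under the other source, including `Unreported`
#' on the EHR side. Constituent counts sum exactly to the aggregate
#' count, and the aggregate prevalence is the count-weighted mean of the
#' constituent prevalences. Intervals are adjusted Wilson intervals.
#'
#' @param records Classified records with `person_key`, `ehr_category`,
#'   `census_category`, `status`.
#' @param outcome_matrix Ever-indicator matrix.
#' @param outcome Single outcome group to disaggregate.
#' @param focus Tibble with columns `labeling` (`"ehr"`/`"census"`) and
#'   `group` naming the aggregates (must be nonempty).
#' @param alpha_family,n_comparisons Interval adjustment.
#' @return Tibble: `labeling`, `group`, `counterpart`, `status`, `n`,
#'   `k`, `p`, `lower`, `upper`, with one `aggregate` row
#'   (`counterpart = "(all)"`) preceding each aggregate's patterns.
#' @export
disaggregate_patterns <- function(records, outcome_matrix, outcome,
                                  focus, alpha_family = 0.05,
                                  n_comparisons = 1L) {
  if (nrow(focus) == 0L) abort("`focus` must name at least one aggregate")
  assert_cols(records, c("person_key", "ehr_category", "census_category",
                         "status"))
  alpha <- bonferroni_level(alpha_family, n_comparisons)
  dat <- inner_join(tibble::as_tibble(records),
                    tibble::as_tibble(outcome_matrix)[, c("person_key", outcome)],
                    by = "person_key")
  purrr::pmap_dfr(focus, function(labeling, group, ...) {
    own <- if (labeling == "ehr") "ehr_category" else "census_category"
    other <- if (labeling == "ehr") "census_category" else "ehr_category"
    members <- dat[as.character(dat[[own]]) == group, , drop = FALSE]
    agg <- tibble(labeling = labeling, group = group, counterpart = "(all)",
                  status = NA_character_, n = nrow(members),
                  k = sum(members[[outcome]]))
    pats <- members |>
      mutate(counterpart = as.character(.data[[other]]),
             status = as.character(status)) |>
      group_by(counterpart, status) |>
      summarise(n = n(), k = sum(.data[[outcome]]), .groups = "drop") |>
      mutate(labeling = labeling, group = group)
    out <- bind_rows(agg, pats)
    ci <- wilson_ci(out$k, pmax(out$n, 1), alpha)
    out |>
      mutate(p = ifelse(.data$n > 0, .data$k / .data$n, NA_real_),
             lower = ifelse(.data$n > 0, ci$lower, NA_real_),
             upper = ifelse(.data$n > 0, ci$upper, NA_real_)) |>
      select(labeling, group, counterpart, status, n, k, p, lower, upper)
  })
}
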