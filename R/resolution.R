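#' Drop allocated census observations
#'
#' Survey processing sometimes imputes ("allocates") a missing
#' race/ethnicity response; allocated responses are not the person's own
#' report and are removed before any prioritization.
#'
#' @param observations Census observation tibble with at least an
#'   `allocated` column (logical or 0/1).
#' @return The non-allocated observations, original order preserved.
#' @export
filter_allocated <- function(observations) {
  assert_cols(observations, "allocated")
  tibble::as_tibble(observations)[!as.logical(observations$allocated), ,
                                  drop = FALSE]
}

harmonize_obs <- function(observations) {
  if (!all(c("category", "race_set") %in% names(observations))) {
    observations <- harmonize_census(observations)
  }
  observations
}

#' Drop same-source-same-year conflicting observations
#'
#' Multiple non-matching responses within one data source and year are
#' indicative of record-linkage error; the whole (person, source, year)
#' group is removed. Groups whose harmonized labels all agree are
#' deduplicated to one representative row. Conflicts are judged on
#' harmonized labels (category plus race set), not raw codes.
#'
#' @param observations Census observations for any number of persons,
#'   with columns `person_key`, `source`, `year`, `hispanic`, `races`
#'   (harmonized columns are added if absent).
#' @return Tibble of surviving observations, one row per surviving
#'   (person, source, year), with an attribute `n_dropped_conflict`
#'   giving the number of removed rows.
#' @export
drop_source_year_conflicts <- function(observations) {
  assert_cols(observations, c("person_key", "source", "year"))
  obs <- harmonize_obs(tibble::as_tibble(observations))
  if (nrow(obs) == 0L) {
    return(structure(obs, n_dropped_conflict = 0L))
  }
  obs <- obs |>
    mutate(.lab = label_key(as.character(category), race_set)) |>
    group_by(person_key, source, year) |>
    mutate(.n_lab = n_distinct(.data$.lab), .grp_n = n()) |>
    ungroup()
  dropped <- sum(obs$.n_lab > 1L)
  out <- obs |>
    filter(.data$.n_lab == 1L) |>
    distinct(person_key, source, year, .keep_all = TRUE) |>
    select(-".lab", -".n_lab", -".grp_n")
  structure(out, n_dropped_conflict = as.integer(dropped))
}

#' Resolve each person's census observations to one prioritized label
#'
#' After removing allocated responses and same-source-year conflicts, the
#' most recent decennial observation is chosen if any survives, otherwise
#' the most recent ACS observation (`priority = "decennial"`, the
#' default); `priority = "recency"` instead takes the globally most
#' recent surviving observation, breaking year ties in favour of the
#' decennial source.
#'
#' @param observations Census observation tibble (`person_key`, `source`
#'   in `DECENNIAL`/`ACS`, `year`, `allocated`, `hispanic`, `races`).
#' @param priority `"decennial"` (source priority dominates recency) or
#'   `"recency"`.
#' @return One row per distinct `person_key` in the input: `person_key`,
#'   `category`, `race_set` (both `NA`/empty when no observation
#'   survived), `source`, `year` (provenance of the chosen observation),
#'   `n_dropped_allocated`, `n_dropped_conflict`.
#' @export
resolve_census <- function(observations, priority = c("decennial", "recency")) {
  priority <- match.arg(priority)
  assert_cols(observations, c("person_key", "source", "year", "allocated"))
  obs <- tibble::as_tibble(observations)
  bad_src <- setdiff(unique(as.character(obs$source)), c("DECENNIAL", "ACS"))
  if (length(bad_src) > 0L) {
    abort(sprintf("unknown census source(s): %s", paste(bad_src, collapse = ", ")))
  }
  persons <- unique(obs$person_key)
  pf_all <- factor(obs$person_key, persons)
  alloc_n <- tabulate(pf_all[as.logical(obs$allocated)],
                      nbins = length(persons))

  kept <- harmonize_obs(filter_allocated(obs))
  conf_n <- integer(length(persons))
  chosen <- kept[0, , drop = FALSE]
  if (nrow(kept) > 0L) {
    lab <- label_key(as.character(kept$category), kept$race_set)
    g <- paste(kept$person_key, kept$source, kept$year, sep = "\r")
    gf <- factor(g)
    n_lab <- tabulate(gf[!duplicated(paste(g, lab, sep = "\r"))],
                      nbins = nlevels(gf))
    conflict <- n_lab[as.integer(gf)] > 1L
    conf_n <- tabulate(factor(kept$person_key, persons)[conflict],
                       nbins = length(persons))
    surv <- kept[!conflict & !duplicated(g), , drop = FALSE]
    ord <- if (priority == "decennial") {
      order(surv$person_key, -(surv$source == "DECENNIAL"), -surv$year)
    } else {
      order(surv$person_key, -surv$year, -(surv$source == "DECENNIAL"))
    }
    surv <- surv[ord, , drop = FALSE]
    chosen <- surv[!duplicated(surv$person_key), , drop = FALSE]
  }

  m <- match(persons, chosen$person_key)
  tibble(
    person_key = persons,
    category = chosen$category[m],
    race_set = ifelse(is.na(m), NA_character_, chosen$race_set[m]),
    source = chosen$source[m],
    year = chosen$year[m],
    n_dropped_allocated = as.integer(alloc_n),
    n_dropped_conflict = as.integer(conf_n)
  )
}

#' Resolve labels within two disjoint source/year windows per person
#'
#' Supports within-census comparisons (e.g. ACS 2019--2022 versus the
#' 2020 decennial census, or two decennial years): the standard
#' allocation and conflict filters and recency rule are applied within
#' each window separately, and only persons with a resolved label in both
#' windows are returned.
#'
#' @param observations Census observation tibble.
#' @param window_a,window_b Lists `list(source =, years = c(lo, hi))`
#'   naming one source and an inclusive year range each. Overlapping
#'   windows (same source and intersecting years) are a configuration
#'   error.
#' @return Tibble `person_key`, `category_a`, `race_set_a`, `category_b`,
#'   `race_set_b`, one row per person present in both windows.
#' @export
pairwise_census_labels <- function(observations, window_a, window_b) {
  check_window <- function(w, nm) {
    if (!is.list(w) || !all(c("source", "years") %in% names(w)) ||
        length(w$years) != 2L) {
      abort(sprintf("`%s` must be list(source =, years = c(lo, hi))", nm))
    }
  }
  check_window(window_a, "window_a")
  check_window(window_b, "window_b")
  if (identical(window_a$source, window_b$source) &&
      max(window_a$years[1], window_b$years[1]) <=
      min(window_a$years[2], window_b$years[2])) {
    abort("pairwise windows overlap; they must be disjoint")
  }
  in_window <- function(obs, w) {
    obs[as.character(obs$source) == w$source &
          obs$year >= w$years[1] & obs$year <= w$years[2], , drop = FALSE]
  }
  obs <- tibble::as_tibble(observations)
  res_a <- resolve_census(in_window(obs, window_a))
  res_b <- resolve_census(in_window(obs, window_b))
  inner_join(
    res_a |> filter(!is.na(category)) |>
      select(person_key, category_a = category, race_set_a = race_set),
    res_b |> filter(!is.na(category)) |>
      select(person_key, category_b = category, race_set_b = race_set),
    by = "person_key"
  )
}
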