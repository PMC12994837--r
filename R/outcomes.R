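icd10_stem_pattern <- "^[A-Z][0-9]{2}"

#' Read an ICD-9/SNOMED to ICD-10 crosswalk table
#'
#' @param path Delimited file with columns `source_code`, `system`
#'   (`ICD9` or `SNOMED`), `icd10_code`. The shipped fixture covers
#'   common primary-care codes; it is a small stand-in for the national
#'   GEM/SNOMED maps, which are external reference data.
#' @return Tibble with those three columns.
#' @export
read_crosswalk <- function(path = system.file("extdata", "icd_crosswalk.csv",
                                              package = "concordkit",
                                              mustWork = TRUE)) {
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = "character"))
  assert_cols(x, c("source_code", "system", "icd10_code"), "crosswalk")
  x
}

#' Collapse clinical codes to 3-digit ICD-10 outcome groups
#'
#' ICD-10 codes are truncated to their first three characters (the
#' general disease group, e.g. every `E11.*` code becomes `E11`); ICD-9
#' and SNOMED codes are first mapped to ICD-10 through the crosswalk and
#' then truncated. Codes absent from the crosswalk return `NA` and are
#' counted in the `n_unmapped` attribute.
#'
#' @param code Character vector of source codes.
#' @param system Matching vector (or scalar) in `ICD9`, `ICD10`, `SNOMED`.
#' @param crosswalk Crosswalk tibble (see [read_crosswalk()]).
#' @return Character vector of 3-character stems (`NA` for unmapped),
#'   with attribute `n_unmapped`. A syntactically malformed ICD-10 input
#'   (no letter + two digits stem) is a coding error.
#' @export
to_icd10_group <- function(code, system, crosswalk = read_crosswalk()) {
  system <- rep_len(as.character(system), length(code))
  if (any(!nzchar(code) | is.na(code))) abort("empty outcome code")
  bad_sys <- setdiff(unique(system), c("ICD9", "ICD10", "SNOMED"))
  if (length(bad_sys) > 0L) {
    abort(sprintf("unknown coding system(s): %s", paste(bad_sys, collapse = ", ")))
  }
  icd10 <- character(length(code))
  is10 <- system == "ICD10"
  icd10[is10] <- code[is10]
  if (any(!is10)) {
    key <- paste(system[!is10], code[!is10])
    lut <- setNames(crosswalk$icd10_code,
                    paste(crosswalk$system, crosswalk$source_code))
    icd10[!is10] <- unname(lut[key])
  }
  stem <- substr(gsub(".", "", icd10, fixed = TRUE), 1L, 3L)
  if (any(is10 & !grepl(icd10_stem_pattern, stem))) {
    abort(sprintf("malformed ICD-10 code(s): %s",
                  paste(unique(code[is10 & !grepl(icd10_stem_pattern, stem)]),
                        collapse = ", ")))
  }
  stem[is.na(icd10)] <- NA_character_
  structure(stem, n_unmapped = sum(is.na(icd10)))
}

#' Per-patient ever-indicators for 3-digit outcome groups
#'
#' For each person and outcome group, the indicator is 1 if at least one
#' of the person's events maps to that group over their whole record
#' window; duplicates and event order are irrelevant. Unmapped events are
#' dropped with a message. Persons in `persons` with no events get
#' all-zero rows.
#'
#' @param events Long tibble `person_key`, `code`, `system`.
#' @param crosswalk Crosswalk tibble.
#' @param persons Optional vector of person keys defining the cohort.
#' @return Wide tibble: `person_key` plus one 0/1 integer column per
#'   outcome group (columns in lexicographic order).
#' @export
ever_indicators <- function(events, crosswalk = read_crosswalk(),
                            persons = NULL) {
  events <- tibble::as_tibble(events)
  assert_cols(events, c("person_key", "code", "system"))
  persons <- persons %||% unique(events$person_key)
  grp <- to_icd10_group(events$code, events$system, crosswalk)
  n_un <- attr(grp, "n_unmapped")
  if (n_un > 0L) message(n_un, " unmapped event(s) dropped")
  mapped <- tibble(person_key = events$person_key,
                   outcome_group = as.character(grp)) |>
    filter(!is.na(outcome_group), person_key %in% persons) |>
    distinct()
  base <- tibble(person_key = persons)
  if (nrow(mapped) == 0L) return(base)
  wide <- mapped |>
    mutate(value = 1L) |>
    tidyr::pivot_wider(names_from = outcome_group, values_from = value,
                       values_fill = 0L, names_sort = TRUE)
  base |>
    left_join(wide, by = "person_key") |>
    mutate(across(-person_key, ~ tidyr::replace_na(.x, 0L)))
}

#' Most prevalent outcome groups
#'
#' Ranks outcome groups by the number of patients ever recorded with
#' them, optionally excluding administrative stems (e.g. `Z` codes,
#' which represent reasons for encounters rather than diagnoses); ties
#' break lexicographically.
#'
#' @param outcome_matrix Ever-indicator matrix from [ever_indicators()].
#' @param k Number of groups to return.
#' @param exclude_prefixes Character vector of stem prefixes to drop
#'   before ranking (e.g. `"Z"`).
#' @return Character vector of at most `k` outcome groups, most
#'   prevalent first; a warning is issued if fewer than `k` exist.
#' @export
top_k_outcomes <- function(outcome_matrix, k = 50L, exclude_prefixes = NULL) {
  if (k < 1L) abort("`k` must be at least 1")
  groups <- setdiff(names(outcome_matrix), "person_key")
  for (p in exclude_prefixes) groups <- groups[!startsWith(groups, p)]
  counts <- vapply(groups, function(g) sum(outcome_matrix[[g]]), numeric(1))
  ord <- order(-counts, groups)
  if (k > length(groups)) {
    warn(sprintf("only %d outcome group(s) available; returning all",
                 length(groups)))
    k <- length(groups)
  }
  groups[ord][seq_len(k)]
}
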