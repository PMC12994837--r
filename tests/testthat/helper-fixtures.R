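# Small builders for classified-record and observation fixtures.

rec_row <- function(ehr, census, ehr_set = "", census_set = "") {
  tibble::tibble(ehr_category = ehr, ehr_race_set = ehr_set,
                 census_category = census, census_race_set = census_set)
}

obs_row <- function(person = "p1", source = "ACS", year = 2015,
                    allocated = FALSE, hispanic = FALSE, races = "White") {
  tibble::tibble(person_key = person, source = source, year = year,
                 allocated = allocated, hispanic = hispanic, races = races)
}

# a tiny, fully hand-checkable classified cohort
tiny_records <- function() {
  dplyr::bind_rows(
    rec_row("White", "White"),
    rec_row("White", "White"),
    rec_row("Black", "Black"),
    rec_row("Hispanic", "Hispanic"),
    rec_row("White", "Hispanic"),
    rec_row("Black", "Multiracial", census_set = "Black;White"),
    rec_row("Black", "Multiracial", census_set = "Asian;White"),
    rec_row("Unreported", "White"),
    rec_row("Unreported", "NHPI"),
    rec_row("Asian", "Asian")
  ) |>
    dplyr::mutate(person_key = sprintf("p%02d", dplyr::row_number()),
                  .before = 1)
}

fast_synth_config <- function(n = 4000L, seed = 11L, ...) {
  synthetic_config(n_patients = n, n_practices = 60L, seed = seed, ...)
}
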