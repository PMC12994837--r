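#' The harmonized race/ethnicity category system
#'
#' The package harmonizes every source coding to the seven mutually
#' exclusive categories of the 1997 Office of Management and Budget (OMB)
#' standard -- Hispanic or Latino (of any race), and the six non-Hispanic
#' categories White, Black, American Indian and Alaska Native (AIAN),
#' Asian, Native Hawaiian and Other Pacific Islander (NHPI), and
#' Multiracial (two or more races) -- plus `Unreported` for records with
#' no usable race/ethnicity information. `Unreported` is never a member
#' of a race set.
#'
#' @return `ck_categories()` returns the eight category codes in fixed
#'   display order; `ck_reported_categories()` the seven reported ones;
#'   `ck_single_races()` the five single-race codes that may appear inside
#'   a multi-race selection.
#' @export
ck_categories <- function() {
  c("Hispanic", "White", "Black", "AIAN", "Asian", "NHPI", "Multiracial",
    "Unreported")
}

#' @rdname ck_categories
#' @export
ck_reported_categories <- function() ck_categories()[1:7]

#' @rdname ck_categories
#' @export
ck_single_races <- function() c("White", "Black", "AIAN", "Asian", "NHPI")

category_factor <- function(x) factor(x, levels = ck_categories())

#' Read a source-code to category mapping table
#'
#' The mapping is a two-column delimited text file (header `source_code`,
#' `category`) that assigns each raw EHR race or ethnicity string to a
#' harmonized category. Ethnicity strings may additionally map to the
#' pseudo-category `NotHispanic` (an affirmative non-Hispanic response,
#' which carries no race information of its own). Matching is
#' case-insensitive after whitespace trimming.
#'
#' @param path Path to the mapping file. The default fixture shipped with
#'   the package covers common EHR dialect strings.
#' @return A tibble with columns `source_code` (normalized) and `category`.
#' @export
read_ehr_mapping <- function(path = default_mapping_path()) {
  m <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = "character"))
  assert_cols(m, c("source_code", "category"), "mapping")
  ok <- c(ck_categories(), "NotHispanic")
  bad <- setdiff(unique(m$category), ok)
  if (length(bad) > 0L) {
    abort(sprintf("mapping contains unknown categories: %s",
                  paste(bad, collapse = ", ")))
  }
  m$source_code <- normalize_code(m$source_code)
  if (anyDuplicated(m$source_code)) {
    abort("mapping contains duplicated source codes")
  }
  m
}

default_mapping_path <- function() {
  system.file("extdata", "ehr_race_mapping.csv", package = "concordkit",
              mustWork = TRUE)
}

normalize_code <- function(x) tolower(trimws(x))

#' Harmonize raw EHR race/ethnicity codings
#'
#' Applies the OMB harmonization rules to a patient table: a Hispanic
#' ethnicity response dominates any race entry; two or more distinct
#' mapped single races yield `Multiracial` with the race set retained;
#' unknown, declined, and blank codings all collapse to `Unreported`.
#'
#' A source string mapped directly to `Multiracial` (some EHRs code it as
#' one option) yields `Multiracial` with an empty race set, since the
#' component races are unobserved; census-side multi-race labels always
#' carry their components (see [harmonize_census()]).
#'
#' @param data A data frame with one row per patient, containing an
#'   ethnicity column and a races column (semicolon-joined raw strings;
#'   empty or `NA` means absent).
#' @param mapping Mapping table as returned by [read_ehr_mapping()].
#' @param ethnicity,races Column names (strings) holding the raw codes.
#' @param strict If `TRUE`, an unmapped source code is an error naming the
#'   code; if `FALSE` (default) unmapped codes are treated as `Unreported`
#'   and reported once via a warning with counts.
#' @return The input tibble with columns `category` (factor over the
#'   eight codes) and `race_set` (canonical semicolon-joined string)
#'   appended.
#' @export
harmonize_ehr <- function(data, mapping = read_ehr_mapping(),
                          ethnicity = "ethnicity", races = "races",
                          strict = FALSE) {
  data <- tibble::as_tibble(data)
  assert_cols(data, c(ethnicity, races))
  lut <- setNames(mapping$category, mapping$source_code)

  look <- function(codes) {
    out <- unname(lut[normalize_code(codes)])
    blank <- !nzchar(trimws(ifelse(is.na(codes), "", codes)))
    out[blank] <- "Unreported"
    unmapped <- is.na(out) & !blank
    if (any(unmapped)) {
      tab <- table(normalize_code(codes[unmapped]))
      if (strict) {
        abort(sprintf("unmapped source code(s): %s",
                      paste(names(tab), collapse = ", ")))
      }
      warn(sprintf("%d code value(s) unmapped, treated as Unreported: %s",
                   length(tab), paste(names(tab), collapse = ", ")))
      out[unmapped] <- "Unreported"
    }
    out
  }

  n <- nrow(data)
  eth_cat <- look(data[[ethnicity]])
  race_tokens <- race_set_split(data[[races]])
  tok <- tibble(row = rep(seq_len(n), lengths(race_tokens)),
                cat = look(unlist(race_tokens, use.names = FALSE)))
  singles <- tok |>
    filter(cat %in% ck_single_races()) |>
    distinct(row, cat) |>
    arrange(row, cat) |>
    group_by(row) |>
    summarise(set = paste(cat, collapse = ";"), k = n(), .groups = "drop")
  set_of <- rep("", n); set_of[singles$row] <- singles$set
  k_of <- integer(n); k_of[singles$row] <- singles$k
  direct_multi <- logical(n)
  direct_multi[unique(tok$row[tok$cat == "Multiracial"])] <- TRUE

  category <- rep("Unreported", n)
  category[direct_multi] <- "Multiracial"
  category[k_of == 1L] <- set_of[k_of == 1L]
  category[k_of >= 2L] <- "Multiracial"
  category[eth_cat == "Hispanic"] <- "Hispanic"
  data$category <- category_factor(category)
  data$race_set <- ifelse(category == "Multiracial" & k_of >= 2L, set_of, "")
  data
}

#' Harmonize census-style race/ethnicity responses
#'
#' A Hispanic flag dominates any race selection; otherwise a single
#' selected race yields that category and two or more yield `Multiracial`
#' with the full race set retained.
#'
#' @param data Data frame with a logical/0-1 Hispanic column and a races
#'   column of semicolon-joined single-race codes
#'   (see [ck_single_races()]).
#' @param hispanic,races Column names (strings).
#' @return Input tibble with `category` and `race_set` columns appended.
#' @export
harmonize_census <- function(data, hispanic = "hispanic", races = "races") {
  data <- tibble::as_tibble(data)
  assert_cols(data, c(hispanic, races))
  hisp <- as.logical(data[[hispanic]])
  tokens <- race_set_split(data[[races]])
  bad <- setdiff(unique(unlist(tokens, use.names = FALSE)), ck_single_races())
  if (length(bad) > 0L) {
    abort(sprintf("unknown census race code(s): %s", paste(bad, collapse = ", ")))
  }
  rs <- race_set_string(tokens)
  n_races <- lengths(race_set_split(rs))
  if (any(!hisp & n_races == 0L)) {
    abort("invalid census observation: hispanic = FALSE with empty race set")
  }
  category <- ifelse(hisp, "Hispanic",
              ifelse(n_races >= 2L, "Multiracial", rs))
  data$category <- category_factor(category)
  data$race_set <- ifelse(category == "Multiracial", rs, "")
  data
}
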