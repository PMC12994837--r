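#' Published-scale summary counts
#'
#' Small count tables transcribed from the public tables of a national
#' linked EHR-census data-quality study, shipped so the package's rate
#' and test operations can be exercised against published worked
#' numbers. The counts were disclosure-protected at source (noise plus
#' rounding to tens), so a few derived percentages differ from exact
#' recomputation by about 0.1 percentage points. The analysis pipeline
#' never reads these tables.
#'
#' @param which `"key_rates"` (name, numerator, denominator),
#'   `"discordant_composition"` (group, ehr_count, census_count), or
#'   `"group_characteristics"` (axis, level, counts per concordance
#'   group).
#' @return A tibble.
#' @export
reported_counts <- function(which = c("key_rates", "discordant_composition",
                                      "group_characteristics")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reported", paste0(which, ".csv"),
                      package = "concordkit", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             check.names = FALSE))
}
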