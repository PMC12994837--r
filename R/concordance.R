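ck_statuses <- function() c("concordant", "partial", "discordant", "nonreporting")

#' Classify per-person concordance between EHR and census labels
#'
#' Each linked person is classified as `concordant` (same harmonized
#' category; two Multiracial labels are concordant regardless of their
#' race sets), `partial` (the EHR single race is one of the distinct
#' races of a Multiracial census label, when `allow_partial = TRUE`),
#' `discordant` (any other mismatch; a Hispanic census label versus an
#' EHR single race is always discordant since ethnicity carries no race
#' set), or `nonreporting` (no usable EHR race/ethnicity). The census
#' label must be reported -- the linked cohort requires valid census
#' race/ethnicity.
#'
#' Partial concordance is defined only in the census-Multiracial
#' direction by default. `mirror_partial = TRUE` additionally treats an
#' EHR Multiracial label containing the census single race as partial;
#' this mirrored rule deviates from the convention of the published
#' analyses this package follows and is off by default.
#'
#' @param data Tibble with columns `ehr_category`, `ehr_race_set`,
#'   `census_category`, `census_race_set`.
#' @param allow_partial Recognize partial concordance (default `TRUE`);
#'   when `FALSE` those pairs are classified `discordant`.
#' @param mirror_partial Also apply the mirrored EHR-Multiracial rule.
#' @return The input tibble with a `status` factor column appended.
#' @export
classify_concordance <- function(data, allow_partial = TRUE,
                                 mirror_partial = FALSE) {
  data <- tibble::as_tibble(data)
  assert_cols(data, c("ehr_category", "ehr_race_set",
                      "census_category", "census_race_set"))
  ehr <- as.character(data$ehr_category)
  cen <- as.character(data$census_category)
  if (any(is.na(cen) | cen == "Unreported")) {
    abort("census label must be reported for every record")
  }
  status <- rep("discordant", nrow(data))
  status[ehr == "Unreported"] <- "nonreporting"
  status[ehr == cen & ehr != "Unreported"] <- "concordant"
  if (allow_partial) {
    in_set <- function(x, set_str) {
      mapply(function(a, s) a %in% s, x, race_set_split(set_str),
             USE.NAMES = FALSE)
    }
    idx <- status == "discordant" & cen == "Multiracial" &
      ehr %in% ck_single_races() & in_set(ehr, data$census_race_set)
    status[idx] <- "partial"
    if (mirror_partial) {
      idx2 <- status == "discordant" & ehr == "Multiracial" &
        cen %in% ck_single_races() & in_set(cen, data$ehr_race_set)
      status[idx2] <- "partial"
    }
  }
  data$status <- factor(status, levels = ck_statuses())
  data
}

tally_weight <- function(data, weight) {
  if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
}

#' Cross-tabulate EHR against census race/ethnicity
#'
#' Builds the person-count matrix of EHR category (rows, including
#' `Unreported`) by census category (columns, reported only), together
#' with row percentages (each row sums to 100) and column percentages
#' (each column sums to 100 over the reported EHR rows, with the
#' `Unreported` row expressed as a percent of the full column including
#' nonreporting persons).
#'
#' @param data Classified records (columns `ehr_category`,
#'   `census_category`); an optional count column allows pre-tallied
#'   input.
#' @param weight Optional name of a count column.
#' @return An object of class `ck_crosstab` with elements `counts`,
#'   `row_pct`, `col_pct` (8 x 7 matrices) and `n` (total persons).
#'   [tidy()][generics::tidy] converts it to a long tibble and
#'   [autoplot()][ggplot2::autoplot] draws the heat-map panels.
#' @export
build_crosstab <- function(data, weight = NULL) {
  data <- tibble::as_tibble(data)
  assert_cols(data, c("ehr_category", "census_category"))
  w <- tally_weight(data, weight)
  rows <- ck_categories()
  cols <- ck_reported_categories()
  counts <- matrix(0, nrow = 8L, ncol = 7L, dimnames = list(rows, cols))
  if (nrow(data) > 0L) {
    tab <- tapply(w, list(factor(as.character(data$ehr_category), rows),
                          factor(as.character(data$census_category), cols)),
                  sum)
    tab[is.na(tab)] <- 0
    counts[rownames(tab), colnames(tab)] <- tab
  }
  row_tot <- rowSums(counts)
  row_pct <- sweep(counts, 1, ifelse(row_tot == 0, 1, row_tot), "/") * 100
  rep_tot <- colSums(counts[1:7, , drop = FALSE])
  full_tot <- colSums(counts)
  col_pct <- counts
  col_pct[1:7, ] <- sweep(counts[1:7, , drop = FALSE], 2,
                          ifelse(rep_tot == 0, 1, rep_tot), "/") * 100
  col_pct[8, ] <- counts[8, ] / ifelse(full_tot == 0, 1, full_tot) * 100
  structure(list(counts = counts, row_pct = row_pct, col_pct = col_pct,
                 n = sum(counts)),
            class = "ck_crosstab")
}

#' @export
print.ck_crosstab <- function(x, ...) {
  cat("Cross-tabulation of", format(x$n, big.mark = ","),
      "linked persons (EHR rows x census columns)\n\n")
  print(round(x$counts))
  invisible(x)
}

#' Overall discordance rate among reporting persons
#'
#' The share of discordant persons among those with race/ethnicity
#' reported in both sources (nonreporting records are excluded from the
#' denominator). With `allow_partial = TRUE`, partially concordant
#' records count as non-discordant; with `FALSE` they are folded into the
#' discordant numerator.
#'
#' @param records Classified records (column `status`), optionally
#'   pre-tallied with a count column.
#' @param allow_partial Treat partial concordance as non-discordant.
#' @param weight Optional name of a count column.
#' @return A proportion in `[0, 1]`.
#' @export
discordance_rate <- function(records, allow_partial = TRUE, weight = NULL) {
  assert_cols(records, "status")
  w <- tally_weight(records, weight)
  st <- as.character(records$status)
  denom <- sum(w[st != "nonreporting"])
  if (denom == 0) abort("discordance rate undefined: no reporting records")
  num <- sum(w[st == "discordant"]) +
    if (allow_partial) 0 else sum(w[st == "partial"])
  num / denom
}

#' EHR missingness rate, overall or by census category
#'
#' The share of persons with census-reported race/ethnicity but no
#' usable race/ethnicity in the EHR source.
#'
#' @param records Classified records (column `status`; `census_category`
#'   required when `by = "census"`).
#' @param by `"overall"` or `"census"` (one rate per census category).
#' @param weight Optional name of a count column.
#' @return A proportion, or a tibble `census_category`, `n`,
#'   `n_nonreporting`, `rate` when `by = "census"`.
#' @export
missingness_rate <- function(records, by = c("overall", "census"),
                             weight = NULL) {
  by <- match.arg(by)
  assert_cols(records, "status")
  w <- tally_weight(records, weight)
  nonrep <- as.character(records$status) == "nonreporting"
  if (by == "overall") {
    if (sum(w) == 0) abort("missingness rate undefined: empty input")
    return(sum(w[nonrep]) / sum(w))
  }
  assert_cols(records, "census_category")
  out <- tibble(census_category = as.character(records$census_category),
                w = w, nonrep = nonrep) |>
    group_by(census_category) |>
    summarise(n = sum(w), n_nonreporting = sum(w[nonrep]), .groups = "drop") |>
    mutate(rate = .data$n_nonreporting / .data$n)
  if (any(out$n == 0)) abort("missingness rate undefined for an empty stratum")
  out
}

#' Composition of the discordant set by race/ethnicity
#'
#' Distributes the discordant persons over categories from either
#' standpoint: the EHR-recorded category or the census-recorded category.
#' Shares are percentages of the discordant total in the input and sum
#' to 100.
#'
#' @param records Classified records, optionally pre-tallied.
#' @param standpoint `"ehr"` or `"census"`.
#' @param allow_partial When `FALSE`, partial records are included in the
#'   discordant set.
#' @param weight Optional name of a count column.
#' @return Tibble `category`, `n`, `share_pct`.
#' @export
discordant_composition <- function(records, standpoint = c("ehr", "census"),
                                   allow_partial = TRUE, weight = NULL) {
  standpoint <- match.arg(standpoint)
  col <- if (standpoint == "ehr") "ehr_category" else "census_category"
  assert_cols(records, c("status", col))
  w <- tally_weight(records, weight)
  st <- as.character(records$status)
  keep <- st == "discordant" | (!allow_partial & st == "partial")
  if (sum(w[keep]) == 0) abort("no discordant records")
  tibble(category = factor(as.character(records[[col]])[keep],
                           levels = ck_reported_categories()),
         w = w[keep]) |>
    group_by(category, .drop = FALSE) |>
    summarise(n = sum(w), .groups = "drop") |>
    mutate(share_pct = 100 * .data$n / sum(.data$n))
}
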