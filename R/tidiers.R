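#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-tabulation into a long tibble
#'
#' @param x A `ck_crosstab`.
#' @param ... Unused.
#' @return Long tibble `ehr_category`, `census_category`, `count`,
#'   `row_pct`, `col_pct`.
#' @export
tidy.ck_crosstab <- function(x, ...) {
  long <- function(m, nm) {
    tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
      setNames(c("ehr_category", "census_category", nm))
  }
  long(x$counts, "count") |>
    left_join(long(x$row_pct, "row_pct"),
              by = c("ehr_category", "census_category")) |>
    left_join(long(x$col_pct, "col_pct"),
              by = c("ehr_category", "census_category")) |>
    mutate(ehr_category = factor(ehr_category, ck_categories()),
           census_category = factor(census_category,
                                    ck_reported_categories())) |>
    arrange(ehr_category, census_category)
}

#' @rdname tidy.ck_crosstab
#' @export
glance.ck_crosstab <- function(x, ...) {
  reporting <- sum(x$counts[1:7, ])
  tibble(n = x$n, n_reporting = reporting,
         n_nonreporting = x$n - reporting,
         discordance = (reporting - sum(diag(x$counts[1:7, ]))) / reporting,
         missingness = (x$n - reporting) / x$n)
}

#' @export
tidy.ck_shift <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ck_shift")
  out
}

#' @export
glance.ck_shift <- function(x, ...) {
  tibble(n_estimates = nrow(x),
         n_significant = sum(x$lower_pp > 0 | x$upper_pp < 0),
         max_abs_shift_pp = max(abs(x$delta_pp)))
}

#' @export
tidy.ck_practice_fits <- function(x, ...) x$slopes

#' @export
glance.ck_practice_fits <- function(x, ...) {
  tibble(model = names(x$fits),
         r.squared = vapply(x$fits, function(f) summary(f)$r.squared,
                            numeric(1)),
         n = vapply(x$fits, function(f) length(f$residuals), numeric(1)))
}
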