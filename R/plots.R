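#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_point
#'   geom_errorbar geom_errorbarh geom_vline facet_wrap labs
#'   scale_fill_gradient theme_minimal theme element_blank
#' @export
ggplot2::autoplot

#' Heat-map panels of an EHR-by-census cross-tabulation
#'
#' @param object A `ck_crosstab`.
#' @param panel `"counts"`, `"row_pct"`, or `"col_pct"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ck_crosstab <- function(object, panel = c("counts", "row_pct",
                                                   "col_pct"), ...) {
  panel <- match.arg(panel)
  d <- tidy(object)
  d$value <- d[[sub("counts", "count", panel)]]
  lab <- c(counts = "persons", row_pct = "% of EHR row",
           col_pct = "% of census column")[[panel]]
  ggplot(d, aes(x = census_category, y = ehr_category, fill = value)) +
    geom_tile() +
    geom_text(aes(label = ifelse(panel == "counts",
                                 format(round(value), big.mark = ","),
                                 sprintf("%.1f", value))), size = 3) +
    scale_fill_gradient(low = "white", high = "#2166ac", name = lab) +
    labs(x = "Census-recorded race/ethnicity",
         y = "EHR-recorded race/ethnicity") +
    theme_minimal()
}

#' Dot-and-interval plot of prevalence shifts
#'
#' Displays, per outcome and group, the percentage-point change in
#' prevalence when switching from EHR-recorded to census-recorded
#' race/ethnicity, with the adjusted delta-method intervals.
#'
#' @param object A `ck_shift` tibble from [prevalence_shift()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ck_shift <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = delta_pp, y = outcome_group, colour = group)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = lower_pp, xmax = upper_pp), height = 0.2) +
    geom_point() +
    labs(x = "Prevalence shift, census minus EHR labeling (pp)",
         y = NULL, colour = "Group") +
    theme_minimal()
}

#' Panel plot of pattern-disaggregated prevalences
#'
#' Shows each focus aggregate's prevalence alongside its constituent
#' recording-pattern cohorts (keyed by counterpart label), with adjusted
#' Wilson intervals and point sizes proportional to log10 cohort size.
#'
#' @param patterns Output of [disaggregate_patterns()].
#' @return A ggplot object.
#' @export
plot_pattern_disaggregation <- function(patterns) {
  d <- patterns |>
    mutate(panel = paste(.data$labeling, .data$group),
           is_agg = .data$counterpart == "(all)",
           lab = ifelse(.data$is_agg, "aggregate",
                        paste0(.data$counterpart, " (", .data$status, ")")))
  ggplot(d, aes(x = 100 * p, y = lab, colour = is_agg)) +
    geom_errorbarh(aes(xmin = 100 * lower, xmax = 100 * upper),
                   height = 0.2) +
    geom_point(aes(size = log10(pmax(n, 1)))) +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "Prevalence (%)", y = NULL, size = "log10 n") +
    theme_minimal() + theme(legend.position = "bottom") +
    ggplot2::guides(colour = "none")
}
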