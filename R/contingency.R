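#' Within-group percentages from a long count table
#'
#' Recomputes contingency-table percentages: given one count per
#' (group, category) cell, returns each cell's percentage of its group
#' total — the form in which cohort baseline characteristics (e.g. HR-HPV
#' positivity per diagnostic group) are reported.
#'
#' @param counts Tibble with grouping, category and count columns.
#' @param group,category,count Column names (strings).
#' @return `counts` with added `total` (group total) and `percent`
#'   (0-100, `100 * count / total`).
#' @export
#' @examples
#' hpv <- read_reference_summary("hpv_status_counts")
#' crosstab_percent(hpv, "group", "status", "n")
crosstab_percent <- function(counts, group = "group", category = "category",
                             count = "n") {
  if (!all(c(group, category, count) %in% names(counts))) {
    abort("Missing grouping, category or count column.")
  }
  if (any(counts[[count]] < 0)) abort("Counts must be non-negative.")
  counts |>
    group_by(.data[[group]]) |>
    mutate(total = sum(.data[[count]]),
           percent = 100 * .data[[count]] / .data$total) |>
    ungroup()
}
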