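#' Lactobacillus-to-anaerobe log-ratio
#'
#' The predefined dysbiosis index: each sample's CLR value for
#' Lactobacillus minus the mean CLR over a curated panel of obligate
#' anaerobic genera. By CLR algebra this equals
#' \eqn{\ln(\text{Lactobacillus proportion} / \text{geometric mean of panel
#' proportions})}. High values indicate Lactobacillus dominance; values
#' near or below zero indicate anaerobe-rich, dysbiotic communities.
#'
#' @param clr CLR tibble from [clr_transform()].
#' @param panel Character vector of anaerobe genus names; intersected with
#'   the table's columns (default [default_anaerobe_panel()]).
#' @return Tibble `sample_id`, `value`.
#' @export
lacto_anaerobe_ratio <- function(clr, panel = default_anaerobe_panel()) {
  if (!"Lactobacillus" %in% names(clr)) {
    abort("CLR table has no Lactobacillus column.")
  }
  panel <- intersect(panel, setdiff(names(clr), "sample_id"))
  if (length(panel) == 0) {
    abort("No panel genus present in the table.")
  }
  lac <- clr_subset_mean(clr, "Lactobacillus")$value
  ana <- clr_subset_mean(clr, panel)$value
  tibble(sample_id = clr$sample_id, value = lac - ana)
}

#' Data-driven composite log-ratio sets
#'
#' Selects the genera consistently increased versus decreased in the case
#' group relative to the control group: a genus joins the increased
#' (decreased) set when its mean CLR difference (case minus control)
#' exceeds `+tau` (falls below `-tau`) and its prevalence is at least
#' `prevalence_min` in the group where it is more abundant.
#'
#' @param abundance Counts tibble.
#' @param metadata Metadata tibble with `diagnosis`.
#' @param case,control Diagnosis labels contrasted (defaults CCU vs
#'   Normal).
#' @param tau Mean-CLR-difference threshold in natural-log units (default
#'   1.0).
#' @param prevalence_min Minimum prevalence in the enriched group (default
#'   0.2).
#' @param pseudocount Passed to [replace_zeros()].
#' @return List with character vectors `increased` and `decreased`; errors
#'   if either is empty.
#' @export
composite_ratio_sets <- function(abundance, metadata, case = "CCU",
                                 control = "Normal", tau = 1.0,
                                 prevalence_min = 0.2, pseudocount = 0.5) {
  aligned <- align_tables(abundance, metadata)
  abundance <- aligned$abundance; metadata <- aligned$metadata
  grp <- as.character(metadata$diagnosis)
  if (!all(c(case, control) %in% grp)) {
    abort("Both case and control groups must be present.")
  }
  genera <- setdiff(names(abundance), "sample_id")
  clr <- clr_transform(replace_zeros(abundance, "counts",
                                     pseudocount = pseudocount))
  cmat <- as.matrix(clr[genera])
  amat <- as.matrix(abundance[genera])
  diff <- colMeans(cmat[grp == case, , drop = FALSE]) -
    colMeans(cmat[grp == control, , drop = FALSE])
  prev_case <- colMeans(amat[grp == case, , drop = FALSE] > 0)
  prev_ctrl <- colMeans(amat[grp == control, , drop = FALSE] > 0)
  increased <- genera[diff > tau & prev_case >= prevalence_min]
  decreased <- genera[diff < -tau & prev_ctrl >= prevalence_min]
  if (length(increased) == 0 || length(decreased) == 0) {
    abort("Empty increased or decreased set; consider lowering `tau`.")
  }
  list(increased = increased, decreased = decreased)
}

#' Composite log-ratio index
#'
#' Mean CLR over the increased set minus mean CLR over the decreased set.
#'
#' @param clr CLR tibble.
#' @param increased,decreased Disjoint non-empty genus sets.
#' @return Tibble `sample_id`, `value`.
#' @export
composite_ratio <- function(clr, increased, decreased) {
  if (length(intersect(increased, decreased)) > 0) {
    abort("Increased and decreased sets must be disjoint.")
  }
  up <- clr_subset_mean(clr, increased)$value
  down <- clr_subset_mean(clr, decreased)$value
  tibble(sample_id = clr$sample_id, value = up - down)
}

#' Compare a log-ratio index across diagnostic groups
#'
#' Kruskal-Wallis across all groups plus pairwise Mann-Whitney comparisons
#' with BH-FDR and Cliff's delta — the same nonparametric stack used for
#' alpha diversity.
#'
#' @param values Tibble `sample_id`, `value` (an index).
#' @param metadata Metadata tibble with `diagnosis`.
#' @return Pairwise comparison tibble (see [group_comparisons()]) with the
#'   Kruskal-Wallis tibble as attribute `"kruskal"` and per-group medians
#'   as attribute `"summary"`.
#' @export
compare_index_groups <- function(values, metadata) {
  df <- left_join(values, metadata, by = "sample_id")
  out <- group_comparisons(df, "value")
  summ <- df |>
    group_by(.data$diagnosis) |>
    summarise(median = median(.data$value),
              q1 = quantile(.data$value, 0.25),
              q3 = quantile(.data$value, 0.75), .groups = "drop")
  attr(out, "summary") <- summ
  out
}

#' ROC curve and AUC for a diagnostic index
#'
#' AUC by the rank (Mann-Whitney) formula with half credit for ties;
#' operating points (sensitivity, specificity) at every unique threshold.
#' By default the positive class is CCU and a *lower* index indicates the
#' positive class (dysbiosis).
#'
#' @param values Numeric index per sample.
#' @param labels Class label per sample.
#' @param positive Label of the positive class (default `"CCU"`).
#' @param direction `"lower"` if low values indicate the positive class,
#'   else `"higher"`.
#' @return List of class `"roc_result"`: `auc`, `points` (tibble
#'   `threshold`, `sensitivity`, `specificity`), `positive`, `direction`.
#' @export
roc_curve <- function(values, labels, positive = "CCU",
                      direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  is_pos <- as.character(labels) == positive
  if (!any(is_pos) || all(is_pos)) abort("Both classes must be non-empty.")
  score <- if (direction == "lower") -values else values
  r <- rank(score)
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(score))
  points <- purrr::map_dfr(c(-Inf, thresholds), function(t) {
    called_pos <- score > t
    tibble(threshold = t,
           sensitivity = sum(called_pos & is_pos) / n_pos,
           specificity = sum(!called_pos & !is_pos) / n_neg)
  })
  structure(list(auc = auc, points = points, positive = positive,
                 direction = direction),
            class = "roc_result")
}
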