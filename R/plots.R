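# ggplot2 figures for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_boxplot geom_jitter
#'   geom_errorbarh geom_vline geom_line geom_abline labs theme_minimal
#'   autoplot facet_wrap
NULL

#' @export
ggplot2::autoplot

#' PCoA ordination plot
#'
#' @param object A `"pcoa_ord"` object.
#' @param metadata Optional metadata tibble; points are coloured by
#'   `diagnosis` when given.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot pcoa_ord
autoplot.pcoa_ord <- function(object, metadata = NULL, ...) {
  df <- object$points
  if (!is.null(metadata)) df <- left_join(df, metadata, by = "sample_id")
  pct <- 100 * object$prop_explained[1:2]
  p <- ggplot(df, aes(x = .data$Axis1, y = .data$Axis2))
  p <- if (!is.null(metadata)) {
    p + geom_point(aes(colour = .data$diagnosis), size = 2)
  } else {
    p + geom_point(size = 2)
  }
  p + labs(x = sprintf("PCoA1 (%.1f%%)", pct[1]),
           y = sprintf("PCoA2 (%.1f%%)", pct[2])) +
    theme_minimal()
}

#' Log-ratio index by diagnostic group
#'
#' Box plots of a per-sample index across diagnosis labels.
#'
#' @param values Tibble `sample_id`, `value`.
#' @param metadata Metadata tibble with `diagnosis`.
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_index_groups <- function(values, metadata, ylab = "log-ratio") {
  df <- left_join(values, metadata, by = "sample_id") |>
    mutate(diagnosis = factor(.data$diagnosis, levels = DIAGNOSIS_LEVELS))
  ggplot(df, aes(x = .data$diagnosis, y = .data$value,
                 fill = .data$diagnosis)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, size = 1) +
    labs(x = NULL, y = ylab) +
    theme_minimal()
}

#' Forest plot of differential-abundance results
#'
#' Log-fold changes with 95% confidence intervals per genus, faceted by
#' contrast.
#'
#' @param fit A `"da_fit"` object.
#' @param genera Optional subset of genera to show.
#' @return A ggplot.
#' @export
plot_da_forest <- function(fit, genera = NULL) {
  df <- fit$results
  if (!is.null(genera)) df <- filter(df, .data$genus %in% genera)
  ggplot(df, aes(x = .data$logfc, y = .data$genus)) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    geom_errorbarh(aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                   height = 0.2) +
    geom_point(aes(colour = .data$significant)) +
    facet_wrap(~contrast) +
    labs(x = "log fold change (natural log)", y = NULL) +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `"roc_result"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot roc_result
autoplot.roc_result <- function(object, ...) {
  df <- arrange(object$points, 1 - .data$specificity, .data$sensitivity)
  ggplot(df, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_line() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}
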