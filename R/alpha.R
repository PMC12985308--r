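#' Per-sample alpha diversity
#'
#' Observed genus richness (number of genera with non-zero abundance) and
#' the Shannon index \eqn{H' = -\sum p_k \ln p_k} (nats) computed on
#' relative abundances.
#'
#' @param tbl Abundance tibble (counts or proportions).
#' @return Tibble `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(tbl) {
  genera <- setdiff(names(tbl), "sample_id")
  mat <- as.matrix(tbl[genera])
  if (any(mat < 0)) abort("Abundances must be non-negative.")
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) {
    abort(paste0("All-zero sample(s): ",
                 paste(tbl$sample_id[zero_rows], collapse = ", ")))
  }
  p <- mat / rowSums(mat)
  shannon <- vapply(seq_len(nrow(p)), function(i) {
    pi <- p[i, p[i, ] > 0]
    -sum(pi * log(pi))
  }, numeric(1))
  tibble(sample_id = tbl$sample_id,
         richness = as.integer(rowSums(mat > 0)),
         shannon = shannon)
}

#' Cliff's delta effect size
#'
#' \eqn{\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\}) / (|x||y|)}, with the
#' conventional magnitude labels: negligible below 0.147, small below 0.33,
#' medium below 0.474, large otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `delta` and `magnitude`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  gt <- sum(vapply(x, function(xi) sum(xi > y), numeric(1)))
  lt <- sum(vapply(x, function(xi) sum(xi < y), numeric(1)))
  delta <- (gt - lt) / (length(x) * length(y))
  list(delta = delta, magnitude = delta_magnitude(delta))
}

delta_magnitude <- function(delta) {
  a <- abs(delta)
  if (a < 0.147) "Negligible"
  else if (a < 0.33) "Small"
  else if (a < 0.474) "Medium"
  else "Large"
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction; p from the chi-square approximation
#' with (number of groups - 1) degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 non-empty groups).
#' @return Tibble `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided. Exact enumeration when the smaller group has at most
#' `exact_max` observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest min-group size for which the exact p is used.
#' @return Tibble `statistic` (U, for `x` over `y`), `p`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment within one testing family. Input p-values must lie
#' in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Pairwise nonparametric group comparisons for one metric
#'
#' For every unordered pair of groups: Mann-Whitney U, BH-FDR across the
#' pair family, and Cliff's delta with magnitude label. The global
#' Kruskal-Wallis result is attached as attribute `"kruskal"`.
#'
#' @param df Tibble holding the metric and the grouping column.
#' @param value Name of the metric column (string).
#' @param group Name of the grouping column (string).
#' @return Tibble `group1`, `group2`, `statistic`, `p`, `q`, `delta`,
#'   `magnitude`, with the Kruskal-Wallis tibble as attribute `"kruskal"`.
#' @export
group_comparisons <- function(df, value, group = "diagnosis") {
  vals <- df[[value]]
  grp <- as.character(df[[group]])
  levels <- intersect(DIAGNOSIS_LEVELS, unique(grp))
  if (length(levels) < 2) levels <- unique(grp)
  kw <- kruskal_wallis(vals, grp)
  pairs <- combn(levels, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- vals[grp == g1]; y <- vals[grp == g2]
    mw <- mann_whitney(x, y)
    cd <- cliffs_delta(x, y)
    tibble(group1 = g1, group2 = g2, statistic = mw$statistic,
           p = mw$p, delta = cd$delta, magnitude = cd$magnitude)
  })
  res$q <- bh_adjust(res$p)
  res <- select(res, "group1", "group2", "statistic", "p", "q",
                "delta", "magnitude")
  attr(res, "kruskal") <- kw
  res
}

#' Alpha diversity group comparison tables
#'
#' Runs [group_comparisons()] for richness and the Shannon index, each as
#' its own FDR family, against the diagnosis labels.
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Metadata tibble with `sample_id`, `diagnosis`.
#' @return Tibble with a `metric` column stacking both comparison tables;
#'   attribute `"kruskal"` holds the per-metric global tests.
#' @export
alpha_comparisons <- function(alpha, metadata) {
  df <- left_join(alpha, metadata, by = "sample_id")
  out <- purrr::map_dfr(c("richness", "shannon"), function(mname) {
    cmp <- group_comparisons(df, mname)
    mutate(cmp, metric = mname, .before = 1)
  })
  kw <- purrr::map_dfr(c("richness", "shannon"), function(mname) {
    mutate(attr(group_comparisons(df, mname), "kruskal"),
           metric = mname, .before = 1)
  })
  attr(out, "kruskal") <- kw
  out
}
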