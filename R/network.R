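# Per-group genus co-occurrence networks: prevalence/variance filtering,
# CLR-Spearman with BH-FDR, thresholded edges, and simple graph metrics.

#' Filter genera for one group's network
#'
#' Keeps genera with within-group prevalence at or above the threshold and
#' non-zero variance, then retains at most `max_taxa` of them with the
#' highest within-group total abundance.
#'
#' @param abundance Abundance tibble.
#' @param sample_ids Samples belonging to the group.
#' @param prevalence_min Inclusive prevalence threshold (default 0.30; the
#'   pipeline uses 0.40 for CCU's smaller group).
#' @param max_taxa Cap on retained genera (default 20).
#' @return Character vector of genus names.
#' @export
filter_network_taxa <- function(abundance, sample_ids, prevalence_min = 0.30,
                                max_taxa = 20) {
  sub <- abundance[abundance$sample_id %in% sample_ids, ]
  if (nrow(sub) == 0) abort("No samples in group.")
  genera <- setdiff(names(sub), "sample_id")
  mat <- as.matrix(sub[genera])
  prev <- colMeans(mat > 0)
  vr <- apply(mat, 2, var)
  ok <- prev >= prevalence_min & vr > 0
  if (!any(ok)) abort("No genus passes the prevalence/variance filter.")
  keep <- genera[ok]
  totals <- colSums(mat[, keep, drop = FALSE])
  keep[order(totals, decreasing = TRUE)][seq_len(min(max_taxa, length(keep)))]
}

#' Pairwise Spearman correlations on CLR values
#'
#' All unordered genus pairs within a group: Spearman's rho as Pearson
#' correlation of average ranks, p from the t approximation with n-2
#' degrees of freedom, BH-FDR across the retained pairs. Pairs involving a
#' constant vector are excluded (logged).
#'
#' @param clr CLR tibble.
#' @param sample_ids Samples belonging to the group.
#' @param genera Genus list (e.g. from [filter_network_taxa()]).
#' @return Tibble `genus1`, `genus2`, `rho`, `p`, `q`.
#' @export
clr_spearman <- function(clr, sample_ids, genera) {
  sub <- clr[clr$sample_id %in% sample_ids, genera, drop = FALSE]
  n <- nrow(sub)
  if (n < 3) abort("Need at least 3 samples for correlations.")
  mat <- as.matrix(sub)
  constant <- apply(mat, 2, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    inform(paste0("Excluding constant genus vector(s): ",
                  paste(genera[constant], collapse = ", ")))
  }
  ranks <- apply(mat, 2, rank)
  pairs <- combn(genera, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    if (constant[g1] || constant[g2]) return(NULL)
    rho <- cor(ranks[, g1], ranks[, g2])
    if (is.na(rho)) return(NULL)
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    tibble(genus1 = g1, genus2 = g2, rho = rho, p = p)
  })
  if (nrow(res) > 0) res$q <- bh_adjust(pmax(res$p, 1e-300)) else res$q <- numeric(0)
  res
}

#' Build a thresholded co-occurrence network
#'
#' Nodes are the full filtered genus list (isolates included); edges are
#' correlation entries with `|rho| >= rho_min` and `q < q_max`, weighted by
#' rho. Density and component count come from [network_metrics()].
#'
#' @param correlations Tibble from [clr_spearman()].
#' @param genera Node list.
#' @param rho_min Absolute correlation threshold (0.60 for Normal/LSIL/
#'   HSIL, 0.70 for CCU in the pipeline defaults).
#' @param q_max FDR threshold (default 0.05, exclusive).
#' @param group Optional group label carried in the result.
#' @return List of class `"cooccurrence_network"`: `group`, `nodes`,
#'   `edges`, `n_nodes`, `n_edges`, `density`, `components`.
#' @export
build_network <- function(correlations, genera, rho_min = 0.60,
                          q_max = 0.05, group = NA_character_) {
  if (rho_min <= 0 || rho_min > 1 || q_max <= 0 || q_max > 1) {
    abort("Thresholds must lie in (0, 1].")
  }
  edges <- filter(correlations, abs(.data$rho) >= rho_min, .data$q < q_max)
  metrics <- network_metrics(genera, edges)
  structure(
    list(group = group, nodes = genera, edges = edges,
         n_nodes = metrics$n_nodes, n_edges = metrics$n_edges,
         density = metrics$density, components = metrics$components),
    class = "cooccurrence_network"
  )
}

#' Graph metrics for a node list and edge list
#'
#' Density is realized over possible edges, \eqn{E / (N(N-1)/2)} for
#' \eqn{N \ge 2} (0 otherwise); connected components are counted over the
#' edge list including isolated nodes.
#'
#' @param nodes Character vector of node names.
#' @param edges Tibble with columns `genus1`, `genus2` (extra columns
#'   ignored).
#' @return Tibble `n_nodes`, `n_edges`, `density`, `components`.
#' @export
network_metrics <- function(nodes, edges) {
  n <- length(nodes)
  e <- nrow(edges)
  density <- if (n >= 2) e / (n * (n - 1) / 2) else 0
  if (n == 0) {
    comp <- 0L
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("genus1", "genus2"), drop = FALSE],
      directed = FALSE, vertices = data.frame(name = nodes)
    )
    comp <- igraph::components(g)$no
  }
  tibble(n_nodes = n, n_edges = e, density = density,
         components = as.integer(comp))
}

#' Per-group co-occurrence networks for a cohort
#'
#' Runs the full network stage for every diagnostic group present:
#' prevalence/variance filtering (0.30, or `ccu_prevalence_min` for CCU),
#' top-`max_taxa` selection, CLR-Spearman with per-group BH-FDR, and edge
#' thresholding (`rho_min`, or `ccu_rho_min` for CCU).
#'
#' @param abundance Counts tibble.
#' @param metadata Metadata tibble.
#' @param prevalence_min,ccu_prevalence_min Prevalence thresholds.
#' @param rho_min,ccu_rho_min Absolute-correlation thresholds.
#' @param q_max FDR threshold (exclusive).
#' @param max_taxa Node cap per group.
#' @param pseudocount Passed to [replace_zeros()].
#' @return Named list of `"cooccurrence_network"` objects, one per group.
#' @export
group_networks <- function(abundance, metadata, prevalence_min = 0.30,
                           ccu_prevalence_min = 0.40, rho_min = 0.60,
                           ccu_rho_min = 0.70, q_max = 0.05, max_taxa = 20,
                           pseudocount = 0.5) {
  aligned <- align_tables(abundance, metadata)
  abundance <- aligned$abundance; metadata <- aligned$metadata
  clr <- clr_transform(replace_zeros(abundance, "counts",
                                     pseudocount = pseudocount))
  groups <- intersect(DIAGNOSIS_LEVELS, unique(metadata$diagnosis))
  out <- purrr::map(groups, function(g) {
    ids <- metadata$sample_id[metadata$diagnosis == g]
    prev <- if (g == "CCU") ccu_prevalence_min else prevalence_min
    rho <- if (g == "CCU") ccu_rho_min else rho_min
    genera <- filter_network_taxa(abundance, ids, prev, max_taxa)
    cors <- clr_spearman(clr, ids, genera)
    build_network(cors, genera, rho_min = rho, q_max = q_max, group = g)
  })
  stats::setNames(out, groups)
}
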