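# Distance-based multivariate tests: PCoA, PERMANOVA, PERMDISP, host screen.
# The permutation machinery is implemented here directly; vegan serves only
# as an independent cross-check in the test suite.

check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("Distance matrix must be square.")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- as.character(seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8) abort("Distance matrix must be symmetric.")
  if (any(diag(d) != 0)) abort("Distance matrix must have a zero diagonal.")
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered
#' matrix \eqn{-\frac{1}{2} J D^2 J}. Axes whose eigenvalue exceeds
#' `1e-8 * max(eigenvalue)` are retained; small negative eigenvalues
#' (rounding noise — Aitchison distances are Euclidean-embeddable) are
#' truncated.
#'
#' @param d Symmetric distance matrix (sample ids as dimnames).
#' @return List of class `"pcoa_ord"`: `points` (tibble `sample_id`,
#'   `Axis1`, ...), `eigenvalues`, `prop_explained`.
#' @export
pcoa_ordination <- function(d) {
  d <- check_dist(d)
  n <- nrow(d)
  if (n < 3) abort("PCoA needs at least 3 samples.")
  cs <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cs$eig
  keep <- which(eig > 1e-8 * max(eig))
  pts <- cs$points[, keep, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(keep))
  structure(
    list(points = dplyr::bind_cols(tibble(sample_id = rownames(d)),
                                   as_tibble(pts)),
         eigenvalues = eig[keep],
         prop_explained = eig[keep] / sum(pmax(eig, 0))),
    class = "pcoa_ord"
  )
}

# Sums of squares from a squared-distance matrix and a list of group index
# vectors: SS_total = sum_{i<j} d^2 / n; SS_within = sum_g sum_{i<j in g} d^2 / n_g.
permanova_ss <- function(d2, idx) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(idx, function(ii) sum(d2[ii, ii]) / (2 * length(ii)),
                          numeric(1)))
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(d2, labels) {
  idx <- split(seq_along(labels), labels)
  ss <- permanova_ss(d2, idx)
  g <- length(idx); n <- length(labels)
  ss_between <- ss["total"] - ss["within"]
  unname((ss_between / (g - 1)) / (ss["within"] / (n - g)))
}

#' PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' Sums of squares are partitioned directly from squared distances
#' (\eqn{SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2}, within-group terms
#' per group), the pseudo-F is
#' \eqn{(SS_B/(g-1)) / (SS_W/(n-g))}, and the p-value counts label
#' permutations whose F reaches the observed one, including the observed
#' labelling: \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + P)}, so
#' \eqn{p \ge 1/(P+1)}.
#'
#' @param d Distance matrix.
#' @param labels Group label per sample (matrix order).
#' @param permutations Number of label permutations P.
#' @param seed Integer seed for the permutation stream.
#' @return List of class `"permanova"`: `pseudo_f`, `r_squared`, `p`,
#'   `permutations`, `n_groups`, `n`.
#' @export
permanova <- function(d, labels, permutations = 999, seed = 1L) {
  d <- check_dist(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(d))
  sizes <- table(labels)
  if (length(sizes) < 2) abort("PERMANOVA needs at least two groups.")
  if (any(sizes < 2)) abort("Every group needs at least two samples.")
  d2 <- d^2
  idx <- split(seq_along(labels), labels)
  ss <- permanova_ss(d2, idx)
  if (ss["within"] <= 1e-12) abort("Degenerate: zero within-group sum of squares.")
  g <- length(idx); n <- length(labels)
  ss_between <- unname(ss["total"] - ss["within"])
  f_obs <- (ss_between / (g - 1)) / (unname(ss["within"]) / (n - g))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  count <- 0L
  for (b in seq_len(permutations)) {
    f_perm <- permanova_f(d2, sample(labels))
    if (f_perm >= f_obs - 1e-12) count <- count + 1L
  }
  structure(
    list(pseudo_f = f_obs,
         r_squared = ss_between / unname(ss["total"]),
         p = (1 + count) / (1 + permutations),
         permutations = permutations, n_groups = g, n = n),
    class = "permanova"
  )
}

#' Pairwise PERMANOVA with FDR correction
#'
#' One PERMANOVA per unordered group pair on the restricted distance
#' sub-matrix, with BH adjustment across the pair family.
#'
#' @inheritParams permanova
#' @return Tibble `group1`, `group2`, `pseudo_f`, `r_squared`, `p`, `q`.
#' @export
pairwise_permanova <- function(d, labels, permutations = 999, seed = 1L) {
  d <- check_dist(d)
  labels <- as.character(labels)
  levels <- intersect(DIAGNOSIS_LEVELS, unique(labels))
  if (length(levels) < 2) levels <- unique(labels)
  pairs <- combn(levels, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    keep <- labels %in% c(g1, g2)
    pv <- permanova(d[keep, keep, drop = FALSE], labels[keep],
                    permutations = permutations,
                    seed = as.integer(seed) + j)
    tibble(group1 = g1, group2 = g2, pseudo_f = pv$pseudo_f,
           r_squared = pv$r_squared, p = pv$p)
  })
  res$q <- bh_adjust(res$p)
  res
}

# Per-sample distance to own-group centroid in the PCoA embedding.
dispersions_from_coords <- function(coords, labels) {
  disp <- numeric(length(labels))
  for (g in unique(labels)) {
    ii <- which(labels == g)
    centroid <- colMeans(coords[ii, , drop = FALSE])
    disp[ii] <- sqrt(rowSums(sweep(coords[ii, , drop = FALSE], 2, centroid)^2))
  }
  disp
}

anova_f <- function(values, labels) {
  grand <- mean(values)
  idx <- split(values, labels)
  g <- length(idx); n <- length(values)
  ss_b <- sum(vapply(idx, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(idx, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ss_w <= 1e-12) return(NA_real_)
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Samples are embedded by PCoA; each sample's dispersion is its Euclidean
#' distance to its group centroid in the embedding. The observed statistic
#' is the one-way ANOVA F on dispersions; the p-value permutes group labels
#' and recomputes centroids and dispersions for every permutation.
#'
#' @inheritParams permanova
#' @return List of class `"permdisp"`: `f`, `p`, `dispersion` (tibble
#'   `group`, `mean_dispersion`), `degenerate` flag.
#' @export
permdisp <- function(d, labels, permutations = 999, seed = 1L) {
  d <- check_dist(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(d))
  sizes <- table(labels)
  if (length(sizes) < 2) abort("PERMDISP needs at least two groups.")
  if (any(sizes < 2)) abort("Every group needs at least two samples.")
  ord <- pcoa_ordination(d)
  coords <- as.matrix(ord$points[setdiff(names(ord$points), "sample_id")])
  disp_obs <- dispersions_from_coords(coords, labels)
  groups <- intersect(DIAGNOSIS_LEVELS, unique(labels))
  if (length(groups) < 2) groups <- unique(labels)
  disp_tbl <- tibble(
    group = groups,
    mean_dispersion = unname(vapply(groups,
                                    function(g) mean(disp_obs[labels == g]),
                                    numeric(1)))
  )
  f_obs <- anova_f(disp_obs, labels)
  if (is.na(f_obs)) {
    warn("PERMDISP degenerate: zero within-group dispersion variance.")
    return(structure(list(f = 0, p = 1, dispersion = disp_tbl,
                          degenerate = TRUE), class = "permdisp"))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  count <- 0L
  for (b in seq_len(permutations)) {
    perm <- sample(labels)
    f_perm <- anova_f(dispersions_from_coords(coords, perm), perm)
    if (!is.na(f_perm) && f_perm >= f_obs - 1e-12) count <- count + 1L
  }
  structure(
    list(f = f_obs, p = (1 + count) / (1 + permutations),
         dispersion = disp_tbl, degenerate = FALSE),
    class = "permdisp"
  )
}

#' Single-factor host screen
#'
#' One independent single-factor PERMANOVA per host factor, each restricted
#' to samples with a non-missing value for that factor. Factors left with
#' fewer than two levels of at least two samples are skipped with a warning.
#' Results are sorted by p-value.
#'
#' @param d Distance matrix.
#' @param metadata Metadata tibble aligned with `d` (`sample_id` order).
#' @param factors Character vector of metadata column names to screen.
#' @inheritParams permanova
#' @return Tibble `factor`, `pseudo_f`, `p`, `n`, sorted by `p`.
#' @export
host_factor_screen <- function(d, metadata, factors, permutations = 999,
                               seed = 1L) {
  d <- check_dist(d)
  stopifnot(all(metadata$sample_id == rownames(d)))
  res <- purrr::map(seq_along(factors), function(j) {
    f <- factors[j]
    if (!f %in% names(metadata)) {
      warn(paste0("Skipping unknown factor: ", f))
      return(NULL)
    }
    vals <- as.character(metadata[[f]])
    keep <- !is.na(vals) & nzchar(vals)
    sizes <- table(vals[keep])
    usable <- names(sizes)[sizes >= 2]
    keep <- keep & vals %in% usable
    if (length(usable) < 2) {
      warn(paste0("Skipping factor with fewer than two usable levels: ", f))
      return(NULL)
    }
    pv <- permanova(d[keep, keep, drop = FALSE], vals[keep],
                    permutations = permutations,
                    seed = as.integer(seed) + j)
    tibble(factor = f, pseudo_f = pv$pseudo_f, p = pv$p, n = pv$n)
  })
  arrange(bind_rows(res), .data$p)
}
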