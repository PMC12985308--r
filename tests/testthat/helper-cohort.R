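# Shared fixtures: small abundance tables and cohort configs built in code.

# Wide abundance tibble from a matrix (rows = samples).
abund_tbl <- function(mat, genera = NULL, ids = NULL) {
  genera <- genera %||% paste0("Genus", seq_len(ncol(mat)))
  ids <- ids %||% sprintf("S%02d", seq_len(nrow(mat)))
  colnames(mat) <- genera
  dplyr::bind_cols(tibble::tibble(sample_id = ids),
                   tibble::as_tibble(mat))
}

# Profile tibble for custom simulations: one row per (group, genus).
make_profiles <- function(groups, genera, means, prevalences) {
  purrr::map_dfr(seq_along(groups), function(i) {
    tibble::tibble(group = groups[i], genus = genera,
                   mean_ra = means[[i]], prevalence = prevalences[[i]])
  })
}

# Two groups drawn from the same composition (null configuration).
# Labels reuse diagnosis levels so downstream defaults apply.
null_two_group_config <- function(n_per_group = 20, n_genera = 12,
                                  concentration = 20) {
  m <- rep(1 / n_genera, n_genera)
  prof <- make_profiles(
    c("Normal", "LSIL"), paste0("Genus", seq_len(n_genera)),
    list(m, m), list(rep(1, n_genera), rep(1, n_genera))
  )
  cohort_config(
    group_sizes = c(Normal = n_per_group, LSIL = n_per_group),
    concentrations = c(Normal = concentration, LSIL = concentration),
    lib_meanlog = log(5000), lib_sdlog = 0.3,
    profiles = prof
  )
}

# Four groups drawn from the same composition (pairwise-null configuration).
null_four_group_config <- function(n_per_group = 8, n_genera = 10,
                                   concentration = 20) {
  m <- rep(1 / n_genera, n_genera)
  groups <- c("Normal", "LSIL", "HSIL", "CCU")
  prof <- make_profiles(groups, paste0("Genus", seq_len(n_genera)),
                        rep(list(m), 4), rep(list(rep(1, n_genera)), 4))
  cohort_config(
    group_sizes = stats::setNames(rep(n_per_group, 4), groups),
    concentrations = stats::setNames(rep(concentration, 4), groups),
    lib_meanlog = log(5000), lib_sdlog = 0.3,
    profiles = prof
  )
}

# A null cohort built from the published Normal profile for both groups.
null_template_config <- function(n_per_group = 20) {
  prof <- default_group_profiles()
  normal <- dplyr::filter(prof, group == "Normal")
  both <- dplyr::bind_rows(normal, dplyr::mutate(normal, group = "LSIL"))
  cohort_config(
    group_sizes = c(Normal = n_per_group, LSIL = n_per_group),
    concentrations = c(Normal = 50, LSIL = 50),
    profiles = both
  )
}

# Independent PERMANOVA pseudo-F, written from the sums-of-squares
# definition without reusing package internals (oracle for small n).
oracle_permanova_f <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- length(labels)
  groups <- unique(labels)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in groups) {
    ii <- which(labels == g)
    ss_within <- ss_within + sum(d2[ii, ii]) / (2 * length(ii))
  }
  ((ss_total - ss_within) / (length(groups) - 1)) /
    (ss_within / (n - length(groups)))
}
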