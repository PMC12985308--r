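#' Default genus profiles for the four diagnostic groups
#'
#' Group-specific mean relative abundance and prevalence for the 17 dominant
#' cervicovaginal genera reported in a published cross-sectional study of
#' cervical disease states, plus a filler genus `"Other"` absorbing the
#' remaining abundance so each group's means sum to exactly 1. These profiles
#' parameterise [simulate_cohort()]: Normal communities are Lactobacillus
#' dominated (mean 90.58%), dominance erodes through LSIL and HSIL, and CCU
#' communities are anaerobe rich with Lactobacillus at 19.52%.
#'
#' @return A tibble with columns `group` (diagnosis label), `genus`,
#'   `mean_ra` (mean relative abundance, fraction in `[0, 1]`) and
#'   `prevalence` (fraction of samples in which the genus was detected).
#'   `"Other"` is assigned prevalence 1.
#' @export
#' @examples
#' default_group_profiles() |> dplyr::filter(genus == "Lactobacillus")
default_group_profiles <- function() {
  genera <- c(
    "Lactobacillus", "Streptococcus", "Limosilactobacillus", "Dialister",
    "Prevotella", "Staphylococcus", "Hoylesella", "Anaerococcus",
    "Peptoniphilus", "Fenollaria", "Campylobacter", "Finegoldia",
    "Fusobacterium", "Enterococcus", "Peptostreptococcus", "Fannyhessea",
    "Pasteurella"
  )
  # mean %, prevalence % per group, genus order as above
  normal_mean <- c(90.58, 4.83, 2.65, 0.52, 0.28, 0.27, 0.13, 0.10, 0.10,
                   0.08, 0.08, 0.07, 0.02, 0.00, 0.00, 0.00, 0.00)
  normal_prev <- c(100, 44, 60, 48, 28, 28, 20, 28, 40, 16, 24, 48, 20, 4,
                   8, 0, 0)
  lsil_mean <- c(83.48, 2.44, 2.87, 2.24, 1.82, 1.17, 0.57, 0.29, 0.52,
                 0.60, 0.24, 0.25, 0.58, 0.13, 0.59, 0.24, 0.00)
  lsil_prev <- c(95.65, 47.83, 47.83, 52.17, 47.83, 39.13, 26.09, 60.87,
                 43.48, 17.39, 39.13, 56.52, 17.39, 21.74, 17.39, 21.74, 0)
  hsil_mean <- c(66.88, 5.91, 0.67, 1.72, 0.56, 0.08, 0.28, 1.81, 1.66,
                 0.38, 0.73, 3.33, 1.95, 0.03, 1.29, 3.93, 0.56)
  hsil_prev <- c(91.67, 45.83, 33.33, 41.67, 25, 33.33, 8.33, 33.33, 33.33,
                 12.5, 16.67, 41.67, 16.67, 4.17, 20.83, 25, 4.17)
  ccu_mean <- c(19.52, 17.44, 0.68, 0.69, 4.06, 1.32, 0.20, 5.16, 1.83,
                0.07, 0.36, 1.71, 4.19, 6.13, 7.93, 5.07, 6.88)
  ccu_prev <- c(80, 60, 30, 40, 70, 30, 40, 70, 70, 20, 50, 60, 30, 30, 50,
                10, 10)

  means <- list(Normal = normal_mean, LSIL = lsil_mean,
                HSIL = hsil_mean, CCU = ccu_mean)
  prevs <- list(Normal = normal_prev, LSIL = lsil_prev,
                HSIL = hsil_prev, CCU = ccu_prev)

  purrr::map_dfr(DIAGNOSIS_LEVELS, function(g) {
    m <- means[[g]] / 100
    p <- prevs[[g]] / 100
    tibble(
      group = g,
      genus = c(genera, "Other"),
      mean_ra = c(m, 1 - sum(m)),
      prevalence = c(p, 1)
    )
  })
}

#' Default curated panel of obligate anaerobic genera
#'
#' The anaerobe side of the Lactobacillus-to-anaerobe log-ratio: Gardnerella,
#' Prevotella, Dialister and related obligate anaerobes commonly implicated
#' in cervicovaginal dysbiosis. Genera absent from a given table are dropped
#' at evaluation time by [lacto_anaerobe_ratio()].
#'
#' @return Character vector of genus names.
#' @export
default_anaerobe_panel <- function() {
  c("Gardnerella", "Prevotella", "Dialister", "Anaerococcus",
    "Peptoniphilus", "Finegoldia", "Fannyhessea", "Fusobacterium",
    "Peptostreptococcus", "Sneathia", "Megasphaera", "Hoylesella")
}

#' Configure a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: per-group sample sizes,
#' Dirichlet concentrations controlling within-group dispersion (smaller =
#' more dispersed), a lognormal library-size model, and the group profiles.
#' Defaults emulate the published cohort: sizes 25/23/24/10 (the microbiome
#' denominators behind the published prevalence percentages), concentrations
#' 50/20/20/5 reproducing the dispersion gradient from tight Normal
#' communities to heterogeneous carcinoma communities, and libraries around
#' 50,000 reads.
#'
#' @param group_sizes Named integer vector of samples per group.
#' @param concentrations Named numeric vector, Dirichlet scale per group
#'   (unitless, > 0).
#' @param lib_meanlog,lib_sdlog Lognormal parameters of reads per sample.
#' @param profiles Tibble as returned by [default_group_profiles()].
#' @param mean_floor Minimum mean relative abundance assigned to a genus
#'   drawn present whose profile mean rounds to zero (see the methods
#'   vignette); fraction, default 5e-4.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(group_sizes = c(Normal = 25, LSIL = 23, HSIL = 24, CCU = 10),
                          concentrations = c(Normal = 50, LSIL = 20, HSIL = 20, CCU = 5),
                          lib_meanlog = log(50000),
                          lib_sdlog = 0.4,
                          profiles = default_group_profiles(),
                          mean_floor = 5e-4) {
  groups <- names(group_sizes)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort("`group_sizes` must be a named vector of per-group sample counts.")
  }
  if (any(group_sizes < 1)) abort("Every group size must be >= 1.")
  if (lib_sdlog < 0) abort("`lib_sdlog` must be >= 0.")
  if (!all(groups %in% names(concentrations))) {
    abort("`concentrations` must name every group in `group_sizes`.")
  }
  if (any(concentrations[groups] <= 0)) abort("Concentrations must be > 0.")
  stopifnot(all(c("group", "genus", "mean_ra", "prevalence") %in% names(profiles)))
  if (!all(groups %in% profiles$group)) {
    abort("`profiles` must contain every group in `group_sizes`.")
  }
  if (any(profiles$mean_ra < 0)) abort("Profile means must be >= 0.")
  if (any(profiles$prevalence < 0 | profiles$prevalence > 1)) {
    abort("Profile prevalences must lie in [0, 1].")
  }
  bad <- profiles$mean_ra > 0 & profiles$prevalence == 0
  if (any(bad)) {
    abort(paste0("Profile rows with positive mean but zero prevalence: ",
                 paste(profiles$genus[bad], collapse = ", ")))
  }
  sums <- tapply(profiles$mean_ra, profiles$group, sum)
  if (any(sums[groups] > 1 + 1e-8)) {
    abort("Profile means must sum to at most 1 within each group.")
  }
  structure(
    list(group_sizes = group_sizes,
         concentrations = concentrations[groups],
         lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
         profiles = profiles, mean_floor = mean_floor),
    class = "cohort_config"
  )
}
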