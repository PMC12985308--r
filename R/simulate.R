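#' Simulate a genus-level cervicovaginal cohort
#'
#' Draws a seeded synthetic cohort from a zero-inflated Dirichlet-multinomial
#' model. For each sample of group \eqn{g}: (1) a presence indicator per
#' genus is drawn Bernoulli(\eqn{\pi_{gk}}); (2) a composition over the
#' present genera is drawn Dirichlet(\eqn{c_g m_{gk}} renormalised to the
#' present set); (3) a library size is drawn lognormal and rounded to an
#' integer of at least 100; (4) counts are drawn multinomial. Lower
#' concentrations \eqn{c_g} produce more dispersed communities, emulating
#' the increase of within-group heterogeneity with disease severity. A
#' sample in which every genus came up absent is re-drawn with
#' Lactobacillus forced present (with a warning).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the draw is fully determined by it.
#' @return A list of class `"cohort"` with elements `abundance` (tibble:
#'   `sample_id` plus one integer count column per genus) and `metadata`
#'   (tibble: `sample_id`, `diagnosis`). Attributes `seed` and `generator`
#'   record provenance.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(), seed = 1)
#' dim(sim$abundance)
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  genera <- unique(config$profiles$genus)
  groups <- names(config$group_sizes)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  rows <- list()
  meta <- list()
  idx <- 0L
  forced <- 0L
  for (g in groups) {
    prof <- config$profiles[config$profiles$group == g, ]
    prof <- prof[match(genera, prof$genus), ]
    m <- prof$mean_ra
    pi_g <- prof$prevalence
    cg <- config$concentrations[[g]]
    for (s in seq_len(config$group_sizes[[g]])) {
      idx <- idx + 1L
      present <- rbinom(length(genera), 1L, pi_g) == 1L
      if (!any(present)) {
        present <- rbinom(length(genera), 1L, pi_g) == 1L
        present[genera == "Lactobacillus"] <- TRUE
        forced <- forced + 1L
      }
      # Present genera whose printed mean rounds to zero get a small floor so
      # presence can materialise as reads.
      alpha_mean <- pmax(m, config$mean_floor) * present
      alpha_mean <- alpha_mean / sum(alpha_mean)
      alpha <- cg * alpha_mean
      comp <- numeric(length(genera))
      gam <- rgamma(sum(present), shape = alpha[present], rate = 1)
      if (all(gam == 0)) gam[] <- 1 # numerically degenerate draw
      comp[present] <- gam / sum(gam)
      lib <- max(100L, as.integer(round(rlnorm(1, config$lib_meanlog,
                                               config$lib_sdlog))))
      counts <- as.integer(rmultinom(1, size = lib, prob = comp))
      rows[[idx]] <- counts
      meta[[idx]] <- g
    }
  }
  if (forced > 0L) {
    warn(sprintf("%d sample(s) drew an all-absent community; re-drawn with Lactobacillus forced present.", forced))
  }
  counts <- do.call(rbind, rows)
  sample_ids <- sprintf("S%03d", seq_len(nrow(counts)))
  abundance <- as_tibble(counts, .name_repair = "minimal")
  names(abundance) <- genera
  abundance <- dplyr::bind_cols(tibble(sample_id = sample_ids), abundance)
  metadata <- tibble(sample_id = sample_ids,
                     diagnosis = unlist(meta))
  structure(
    list(abundance = abundance, metadata = metadata),
    class = "cohort",
    seed = as.integer(seed),
    generator = "Mersenne-Twister (base R)"
  )
}
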