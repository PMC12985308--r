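#' Configure a full pipeline run
#'
#' Flat key-value configuration for [run_pipeline()]. Either supply input
#' TSV paths (`abundance_path`, `metadata_path`) or leave them `NULL` to
#' simulate a cohort from [cohort_config()].
#'
#' @param abundance_path,metadata_path Input TSVs, or `NULL` to simulate.
#' @param simulation A [cohort_config()] used when simulating.
#' @param seed Integer seed driving simulation and every permutation test.
#' @param permutations Label permutations for PERMANOVA/PERMDISP/host
#'   screen (default 9999).
#' @param pseudocount Zero-replacement pseudocount on counts.
#' @param da_q Differential-abundance significance threshold (default
#'   0.10).
#' @param anaerobe_panel Panel for the Lactobacillus-to-anaerobe ratio.
#' @param host_factors Metadata columns for the host screen (default: all
#'   columns besides `sample_id` and `diagnosis`).
#' @param outdir Output directory for result TSVs.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(abundance_path = NULL, metadata_path = NULL,
                            simulation = cohort_config(), seed = 1L,
                            permutations = 9999, pseudocount = 0.5,
                            da_q = 0.10,
                            anaerobe_panel = default_anaerobe_panel(),
                            host_factors = NULL, outdir = tempdir()) {
  if (permutations < 99) abort("`permutations` must be at least 99.")
  if (da_q <= 0 || da_q > 1) abort("`da_q` must lie in (0, 1].")
  structure(
    list(abundance_path = abundance_path, metadata_path = metadata_path,
         simulation = simulation, seed = as.integer(seed),
         permutations = permutations, pseudocount = pseudocount,
         da_q = da_q, anaerobe_panel = anaerobe_panel,
         host_factors = host_factors, outdir = outdir),
    class = "pipeline_config"
  )
}

write_result <- function(tbl, path, provenance) {
  writeLines(c(provenance_header(provenance),
               paste(names(tbl), collapse = "\t")), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> align -> zero replacement + CLR -> alpha
#' diversity -> beta diversity (PCoA, global and pairwise PERMANOVA,
#' PERMDISP, host screen) -> differential abundance -> log-ratio indices
#' with ROC -> per-group co-occurrence networks, writing one TSV per stage
#' to `config$outdir`. Every output carries a provenance header (seed,
#' package version, key parameters). Re-running with the same config is
#' reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `files`, the named
#'   vector of written paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "cervicomp",
               version = as.character(utils::packageVersion("cervicomp")),
               seed = config$seed, permutations = config$permutations,
               pseudocount = config$pseudocount)
  out <- function(name) file.path(config$outdir, paste0(name, ".tsv"))
  files <- character()

  if (is.null(config$abundance_path)) {
    sim <- simulate_cohort(config$simulation, seed = config$seed)
    abundance <- sim$abundance; metadata <- sim$metadata
    files["abundance"] <- write_abundance(abundance, out("abundance"),
                                          "counts", prov)
    files["metadata"] <- write_metadata(metadata, out("metadata"), prov)
  } else {
    abundance <- read_abundance(config$abundance_path, "counts")
    metadata <- read_metadata(config$metadata_path)
  }
  aligned <- align_tables(abundance, metadata)
  abundance <- aligned$abundance; metadata <- aligned$metadata

  props <- replace_zeros(abundance, "counts",
                         pseudocount = config$pseudocount)
  clr <- clr_transform(props)
  d <- aitchison_distance(clr)

  alpha <- alpha_diversity(abundance)
  files["alpha"] <- write_result(alpha, out("alpha"), prov)
  alpha_cmp <- alpha_comparisons(alpha, metadata)
  files["alpha_comparisons"] <- write_result(alpha_cmp,
                                             out("alpha_comparisons"), prov)

  ord <- pcoa_ordination(d)
  files["ordination"] <- write_result(ord$points, out("ordination"), prov)
  global <- permanova(d, metadata$diagnosis,
                      permutations = config$permutations,
                      seed = config$seed)
  files["permanova"] <- write_result(glance(global), out("permanova"), prov)
  pairwise <- pairwise_permanova(d, metadata$diagnosis,
                                 permutations = config$permutations,
                                 seed = config$seed)
  files["pairwise_permanova"] <- write_result(pairwise,
                                              out("pairwise_permanova"), prov)
  disp <- permdisp(d, metadata$diagnosis,
                   permutations = config$permutations, seed = config$seed)
  files["permdisp"] <- write_result(
    dplyr::bind_cols(glance(disp)[, c("statistic", "p.value")],
                     tidyr::pivot_wider(disp$dispersion,
                                        names_from = "group",
                                        values_from = "mean_dispersion")),
    out("permdisp"), prov)

  host_factors <- config$host_factors %||%
    setdiff(names(metadata), c("sample_id", "diagnosis"))
  host <- NULL
  if (length(host_factors) > 0) {
    host <- host_factor_screen(d, metadata, host_factors,
                               permutations = config$permutations,
                               seed = config$seed)
    files["host_screen"] <- write_result(host, out("host_screen"), prov)
  }

  da <- bias_corrected_da(abundance, metadata, q_threshold = config$da_q)
  files["differential_abundance"] <- write_result(
    da$results, out("differential_abundance"), prov)
  files["da_global"] <- write_result(da$global, out("da_global"), prov)

  la <- lacto_anaerobe_ratio(clr, config$anaerobe_panel)
  files["la_logratio"] <- write_result(la, out("la_logratio"), prov)
  la_cmp <- compare_index_groups(la, metadata)
  files["la_comparisons"] <- write_result(la_cmp, out("la_comparisons"), prov)
  roc <- roc_curve(left_join(la, metadata, by = "sample_id")$value,
                   left_join(la, metadata, by = "sample_id")$diagnosis)
  files["roc_points"] <- write_result(roc$points, out("roc_points"), prov)

  nets <- group_networks(abundance, metadata,
                         pseudocount = config$pseudocount)
  net_metrics <- purrr::map_dfr(nets, glance)
  files["network_metrics"] <- write_result(net_metrics,
                                           out("network_metrics"), prov)
  net_edges <- purrr::map_dfr(nets, function(nw) {
    if (nrow(nw$edges) == 0) return(NULL)
    mutate(nw$edges, group = nw$group, .before = 1)
  })
  if (is.null(net_edges) || nrow(net_edges) == 0) {
    net_edges <- tibble(group = character(), genus1 = character(),
                        genus2 = character(), rho = numeric(),
                        p = numeric(), q = numeric())
  }
  files["network_edges"] <- write_result(net_edges, out("network_edges"),
                                         prov)

  invisible(list(
    abundance = abundance, metadata = metadata, clr = clr, distance = d,
    alpha = alpha, alpha_comparisons = alpha_cmp, ordination = ord,
    permanova = global, pairwise_permanova = pairwise, permdisp = disp,
    host_screen = host, da = da, la_logratio = la,
    la_comparisons = la_cmp, roc = roc, networks = nets, files = files
  ))
}
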