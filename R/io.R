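#' Validate an abundance table
#'
#' Checks the wide abundance layout used throughout the package: a
#' `sample_id` column of unique strings followed by one non-negative numeric
#' column per genus (unique names). In `"counts"` mode all values must be
#' integers; in `"proportions"` mode each row must sum to 1 within 1e-9.
#'
#' @param tbl Tibble, `sample_id` plus genus columns.
#' @param mode `"counts"` or `"proportions"`.
#' @return `tbl`, invisibly, after validation.
#' @export
validate_abundance <- function(tbl, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (!"sample_id" %in% names(tbl)) abort("Abundance table needs a `sample_id` column.")
  ids <- as.character(tbl$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample id: ", ids[duplicated(ids)][1]))
  }
  genera <- setdiff(names(tbl), "sample_id")
  if (length(genera) == 0) abort("Abundance table has no genus columns.")
  if (anyDuplicated(genera)) {
    abort(paste0("Duplicate genus column: ", genera[duplicated(genera)][1]))
  }
  mat <- as.matrix(tbl[genera])
  if (!is.numeric(mat)) abort("Genus columns must be numeric.")
  if (anyNA(mat)) abort("Abundance table contains missing values.")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("Negative abundance at sample '%s', genus '%s'.",
                  ids[neg[1, 1]], genera[neg[1, 2]]))
  }
  if (mode == "counts") {
    off <- which(abs(mat - round(mat)) > 1e-9, arr.ind = TRUE)
    if (nrow(off) > 0) {
      abort(sprintf("Non-integer count at sample '%s', genus '%s'.",
                    ids[off[1, 1]], genera[off[1, 2]]))
    }
  } else {
    rs <- rowSums(mat)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad) > 0) {
      abort(sprintf("Row of sample '%s' sums to %.12g, not 1.",
                    ids[bad[1]], rs[bad[1]]))
    }
  }
  invisible(tbl)
}

#' Read a genus abundance table from TSV
#'
#' Expects tab-separated text with the sample identifier in the first column
#' and one header-named column per genus. Lines starting with `#` (the
#' provenance header written by [write_abundance()]) are skipped. Counts are
#' coerced to integer; non-integer values are rejected.
#'
#' @param path File path.
#' @inheritParams validate_abundance
#' @return A validated abundance tibble.
#' @export
read_abundance <- function(path, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tbl)[1] <- "sample_id"
  tbl$sample_id <- as.character(tbl$sample_id)
  validate_abundance(tbl, mode)
  if (mode == "counts") {
    tbl <- mutate(tbl, across(-"sample_id", ~ as.integer(round(.x))))
  }
  tbl
}

# Provenance header lines for result TSVs.
provenance_header <- function(provenance) {
  if (length(provenance) == 0) return(character())
  sprintf("# %s: %s", names(provenance),
          vapply(provenance, function(x) paste(format(x), collapse = " "),
                 character(1)))
}

#' Write a genus abundance table to TSV
#'
#' Counts are written exactly; proportions with 12 significant digits so a
#' read/write round trip is the identity at that precision. Provenance
#' key-value pairs are written as `#`-prefixed header lines.
#'
#' @param tbl Abundance tibble.
#' @param path Output path.
#' @inheritParams validate_abundance
#' @param provenance Named list recorded as header comments (seed, version,
#'   parameters, ...).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tbl, path, mode = c("counts", "proportions"),
                            provenance = list()) {
  mode <- match.arg(mode)
  validate_abundance(tbl, mode)
  out <- tbl
  if (mode == "proportions") {
    out <- mutate(out, across(-"sample_id", ~ signif(.x, 12)))
  }
  writeLines(c(provenance_header(provenance),
               paste(names(out), collapse = "\t")), path)
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id` and `diagnosis`, then any number of host
#' factor columns. Unknown diagnosis labels are rejected; samples with a
#' missing diagnosis are dropped with a warning. Empty fields become `NA`.
#'
#' @param path File path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  if (!all(c("sample_id", "diagnosis") %in% names(tbl))) {
    abort("Metadata needs `sample_id` and `diagnosis` columns.")
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  if (anyDuplicated(tbl$sample_id)) abort("Duplicate sample ids in metadata.")
  missing_dx <- is.na(tbl$diagnosis)
  if (any(missing_dx)) {
    warn(sprintf("Dropping %d sample(s) with missing diagnosis: %s",
                 sum(missing_dx),
                 paste(tbl$sample_id[missing_dx], collapse = ", ")))
    tbl <- tbl[!missing_dx, ]
  }
  bad <- setdiff(unique(tbl$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown diagnosis label(s): ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' Write sample metadata to TSV
#'
#' @param tbl Metadata tibble (`sample_id`, `diagnosis`, factors).
#' @param path Output path.
#' @param provenance Named list recorded as `#` header comments.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(tbl, path, provenance = list()) {
  writeLines(c(provenance_header(provenance),
               paste(names(tbl), collapse = "\t")), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Align an abundance table with sample metadata
#'
#' Restricts both tables to the intersection of their sample ids, in the
#' abundance table's order, logging any dropped ids.
#'
#' @param abundance Abundance tibble.
#' @param metadata Metadata tibble.
#' @return List with aligned `abundance` and `metadata`.
#' @export
align_tables <- function(abundance, metadata) {
  keep <- intersect(abundance$sample_id, metadata$sample_id)
  if (length(keep) == 0) abort("Abundance and metadata share no sample ids.")
  dropped <- setdiff(union(abundance$sample_id, metadata$sample_id), keep)
  if (length(dropped) > 0) {
    inform(paste0("align_tables: dropping ", length(dropped),
                  " unmatched sample(s): ", paste(dropped, collapse = ", ")))
  }
  list(
    abundance = abundance[match(keep, abundance$sample_id), ],
    metadata = metadata[match(keep, metadata$sample_id), ]
  )
}

#' Read a bundled reference summary table
#'
#' The package ships small plain-text summaries from a published
#' cervicovaginal microbiome study, used by the worked examples and the
#' acceptance checks: `"hpv_status_counts"` (HR-HPV status counts per
#' diagnostic group), `"network_nodes"` (number of genera retained per group
#' network) and `"network_edges"` (the significant co-occurrence edges per
#' group with Spearman's rho).
#'
#' @param name One of `"hpv_status_counts"`, `"network_nodes"`,
#'   `"network_edges"`.
#' @return A tibble.
#' @export
read_reference_summary <- function(name = c("hpv_status_counts",
                                            "network_nodes",
                                            "network_edges")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cervicomp")
  if (!nzchar(path)) abort(paste0("Bundled summary not found: ", name))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
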