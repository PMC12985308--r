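#' Replace zeros and close to proportions
#'
#' Compositions must be strictly positive before the centered log-ratio
#' transform. Counts get a pseudocount added to every cell and are then
#' closed (divided by the row total); proportions get multiplicative
#' replacement: each zero becomes `delta` and the non-zero parts of that row
#' are rescaled by `1 - z * delta` (`z` = zeros in the row) so the row still
#' sums to 1.
#'
#' @param tbl Abundance tibble (`sample_id` + genus columns).
#' @param mode `"counts"` or `"proportions"`.
#' @param pseudocount Added to every count before closure (counts mode).
#' @param delta Replacement value for zero proportions (proportions mode).
#' @return A strictly positive abundance tibble in proportions mode.
#' @export
replace_zeros <- function(tbl, mode = c("counts", "proportions"),
                          pseudocount = 0.5, delta = 1e-6) {
  mode <- match.arg(mode)
  validate_abundance(tbl, mode)
  mat <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  zero_rows <- rowSums(mat) == 0
  if (any(zero_rows)) {
    abort(paste0("Sample(s) with all-zero abundance: ",
                 paste(tbl$sample_id[zero_rows], collapse = ", ")))
  }
  if (mode == "counts") {
    mat <- mat + pseudocount
    mat <- mat / rowSums(mat)
  } else {
    for (i in seq_len(nrow(mat))) {
      z <- mat[i, ] == 0
      if (any(z)) {
        mat[i, !z] <- mat[i, !z] * (1 - sum(z) * delta)
        mat[i, z] <- delta
      }
    }
  }
  out <- as_tibble(mat)
  dplyr::bind_cols(tbl["sample_id"], out)
}

#' Centered log-ratio transform
#'
#' Maps each strictly positive composition \eqn{x} to
#' \eqn{\ln(x_k / g(x))} with \eqn{g(x)} the row geometric mean. Every
#' output row sums to zero, so Euclidean geometry (and hence the Aitchison
#' distance) is valid on the result. Natural logarithm throughout.
#'
#' @param props Strictly positive proportions tibble (rows sum to 1).
#' @return CLR tibble (`sample_id` + genus columns; rows sum to 0).
#' @export
clr_transform <- function(props) {
  genera <- setdiff(names(props), "sample_id")
  mat <- as.matrix(props[genera])
  if (any(mat <= 0)) abort("CLR requires strictly positive entries.")
  lx <- log(mat)
  clr <- lx - rowMeans(lx)
  dplyr::bind_cols(props["sample_id"], as_tibble(clr))
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distance between CLR-transformed samples — the beta
#' diversity metric used throughout the pipeline.
#'
#' @param clr CLR tibble from [clr_transform()].
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
aitchison_distance <- function(clr) {
  mat <- as.matrix(clr[setdiff(names(clr), "sample_id")])
  rownames(mat) <- clr$sample_id
  as.matrix(stats::dist(mat, method = "euclidean"))
}

#' Mean CLR over a genus subset
#'
#' The arithmetic mean of CLR values over a subset equals the log of the
#' subset's geometric mean divided by the whole-composition geometric mean —
#' the building block of the log-ratio indices.
#'
#' @param clr CLR tibble.
#' @param genera Non-empty character vector of genus names present in `clr`.
#' @return Tibble `sample_id`, `value`.
#' @export
clr_subset_mean <- function(clr, genera) {
  if (length(genera) == 0) abort("Genus subset must be non-empty.")
  missing <- setdiff(genera, names(clr))
  if (length(missing) > 0) {
    abort(paste0("Unknown genus: ", paste(missing, collapse = ", ")))
  }
  mat <- as.matrix(clr[genera])
  tibble(sample_id = clr$sample_id, value = rowMeans(mat))
}
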