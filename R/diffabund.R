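#' Bias-corrected compositional differential abundance
#'
#' A differential-abundance estimator in the ANCOM-BC family: observed log
#' abundances are modelled as a per-genus group mean plus a per-sample
#' sampling-fraction offset, \eqn{y_{jk} = \beta_{g(j),k} + d_j +
#' \varepsilon_{jk}} with \eqn{y = \ln(count + pseudocount)}. Group means
#' and offsets are estimated by alternating least squares; each contrast's
#' log-fold changes are then centred by subtracting their median across
#' genera (the bias term — valid when most genera are non-differential).
#' Wald tests use the two-group standard error from per-genus residual
#' variances; BH-FDR is applied within each contrast family, and a global
#' chi-square test per genus combines all non-reference contrasts. This is
#' a simplified member of the method family, not a verbatim ANCOM-BC2
#' reimplementation (no structural-zero detection, sensitivity scores or
#' mixed models).
#'
#' @param abundance Counts tibble (`sample_id` + genus columns).
#' @param metadata Metadata tibble with `diagnosis`.
#' @param reference Reference group for the global test (default
#'   `"Normal"`).
#' @param contrasts List of `c(group1, group2)` pairs; logFC is group1
#'   minus group2. Defaults to the four severity contrasts
#'   CCU-Normal, CCU-LSIL, HSIL-LSIL, LSIL-Normal (those present).
#' @param pseudocount Added inside the log (default 1).
#' @param q_threshold Significance threshold on the BH q-value (default
#'   0.10).
#' @param tol,max_iter Convergence controls of the alternating fit.
#' @return List of class `"da_fit"`: `results` (tibble `genus`, `contrast`,
#'   `logfc`, `se`, `ci_lo`, `ci_hi`, `p`, `q`, `significant`), `global`
#'   (tibble `genus`, `statistic`, `df`, `p`, `q`), plus fit internals.
#' @export
bias_corrected_da <- function(abundance, metadata, reference = "Normal",
                              contrasts = NULL, pseudocount = 1,
                              q_threshold = 0.10, tol = 1e-6,
                              max_iter = 100) {
  validate_abundance(abundance, "counts")
  aligned <- align_tables(abundance, metadata)
  abundance <- aligned$abundance; metadata <- aligned$metadata
  genera <- setdiff(names(abundance), "sample_id")
  counts <- as.matrix(abundance[genera])
  grp <- as.character(metadata$diagnosis)
  sizes <- table(grp)
  if (length(sizes) < 2) abort("Need at least two groups.")
  if (any(sizes < 3)) abort("Every group needs at least three samples.")
  if (!reference %in% names(sizes)) abort("Reference group absent from data.")
  groups <- intersect(DIAGNOSIS_LEVELS, names(sizes))
  if (length(groups) < 2) groups <- names(sizes)

  y <- log(counts + pseudocount)
  n <- nrow(y); m <- ncol(y)
  d_hat <- numeric(n)
  beta <- matrix(0, length(groups), m, dimnames = list(groups, genera))
  for (it in seq_len(max_iter)) {
    for (g in groups) {
      jj <- grp == g
      beta[g, ] <- colMeans(y[jj, , drop = FALSE] - d_hat[jj])
    }
    d_new <- rowMeans(y - beta[grp, , drop = FALSE])
    if (max(abs(d_new - d_hat)) < tol) { d_hat <- d_new; break }
    d_hat <- d_new
  }
  resid <- y - beta[grp, , drop = FALSE] - d_hat
  s2 <- matrix(NA_real_, length(groups), m, dimnames = list(groups, genera))
  for (g in groups) {
    s2[g, ] <- apply(resid[grp == g, , drop = FALSE], 2, var)
  }

  if (is.null(contrasts)) {
    contrasts <- Filter(
      function(pr) all(pr %in% groups),
      list(c("CCU", "Normal"), c("CCU", "LSIL"),
           c("HSIL", "LSIL"), c("LSIL", "Normal"))
    )
    if (length(contrasts) == 0) {
      contrasts <- list(c(groups[2], groups[1]))
    }
  }

  contrast_tbl <- function(g1, g2) {
    estimable <- colSums(counts[grp == g1, , drop = FALSE]) > 0 |
      colSums(counts[grp == g2, , drop = FALSE]) > 0
    raw <- beta[g1, ] - beta[g2, ]
    bias <- median(raw[estimable])
    lfc <- raw - bias
    se <- sqrt(s2[g1, ] / sizes[[g1]] + s2[g2, ] / sizes[[g2]])
    z <- lfc / se
    p <- 2 * pnorm(-abs(z))
    out <- tibble(
      genus = genera,
      contrast = paste(g1, "vs", g2),
      logfc = unname(lfc), se = unname(se),
      ci_lo = unname(lfc - qnorm(0.975) * se),
      ci_hi = unname(lfc + qnorm(0.975) * se),
      p = unname(p), estimable = estimable
    )
    out$q <- NA_real_
    out$q[estimable] <- bh_adjust(pmax(out$p[estimable], 1e-300))
    out$significant <- !is.na(out$q) & out$q <= q_threshold
    out
  }
  results <- purrr::map_dfr(contrasts, ~ contrast_tbl(.x[1], .x[2]))

  # Global Wald test: all non-reference groups vs the reference, each
  # bias-corrected, combined as an independent-coordinate chi-square.
  others <- setdiff(groups, reference)
  chi <- numeric(m)
  for (g in others) {
    raw <- beta[g, ] - beta[reference, ]
    lfc <- raw - median(raw)
    se <- sqrt(s2[g, ] / sizes[[g]] + s2[reference, ] / sizes[[reference]])
    chi <- chi + (lfc / se)^2
  }
  gp <- pchisq(chi, df = length(others), lower.tail = FALSE)
  global <- tibble(genus = genera, statistic = chi,
                   df = length(others), p = gp,
                   q = bh_adjust(pmax(gp, 1e-300)))

  structure(
    list(results = results, global = global, beta = beta, offsets = d_hat,
         reference = reference, q_threshold = q_threshold,
         pseudocount = pseudocount),
    class = "da_fit"
  )
}
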