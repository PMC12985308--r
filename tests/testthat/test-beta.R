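test_that("PCoA embeds Euclidean distances exactly", {
  pts <- c(0, 1, 3, 7)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("S", 1:4)
  ord <- pcoa_ordination(d)
  expect_equal(length(ord$eigenvalues), 1) # collinear points: one axis
  coords <- as.matrix(ord$points[, -1])
  expect_equal(as.matrix(dist(coords)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pcoa_ordination(d[1:2, 1:2]), "at least 3")
})

test_that("Aitchison distances are Euclidean-embeddable and recoverable", {
  sim <- simulate_cohort(cohort_config(group_sizes = c(Normal = 5),
                                       concentrations = c(Normal = 20)),
                         seed = 12)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  ord <- pcoa_ordination(d)
  expect_true(all(ord$eigenvalues > 0))
  coords <- as.matrix(ord$points[, -1])
  expect_equal(as.matrix(dist(coords)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9)) # sorted descending
})

test_that("PERMANOVA agrees with vegan and partitions variance exactly", {
  sim <- simulate_cohort(cohort_config(), seed = 13)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  pv <- permanova(d, sim$metadata$diagnosis, permutations = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ diagnosis, data = sim$metadata,
                       permutations = 49)
  expect_equal(pv$pseudo_f, ad$F[1], tolerance = 1e-10)
  expect_equal(pv$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_gte(pv$p, 1 / 100)
  expect_true(pv$r_squared >= 0 && pv$r_squared <= 1)
})

test_that("PERMANOVA p matches exhaustive enumeration for small n", {
  set.seed(30)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("S", 1:6)
  labels <- rep(c("a", "b"), each = 3)
  f_obs <- oracle_permanova_f(d, labels)
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(ii) {
    lab <- rep("b", 6); lab[ii] <- "a"
    oracle_permanova_f(d, lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  pv <- permanova(d, labels, permutations = 10000, seed = 3)
  expect_equal(pv$pseudo_f, f_obs, tolerance = 1e-12)
  expect_lt(abs(pv$p - p_exact), 0.02)
})

test_that("PERMANOVA hits the p-value floor for separated clusters and 1 for symmetry", {
  x <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
             matrix(rnorm(20, 50, 0.05), 10, 2))
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("S", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  pv <- permanova(d, labels, permutations = 199, seed = 2)
  expect_equal(pv$p, 1 / 200)

  deq <- matrix(1, 6, 6) - diag(6)
  rownames(deq) <- colnames(deq) <- paste0("S", 1:6)
  pveq <- permanova(deq, rep(c("a", "b"), each = 3),
                    permutations = 99, seed = 1)
  expect_equal(pveq$p, 1)
})

test_that("PERMANOVA statistic is invariant to joint reordering", {
  sim <- simulate_cohort(cohort_config(group_sizes = c(Normal = 8, CCU = 8),
                                       concentrations = c(Normal = 30, CCU = 10)),
                         seed = 15)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  labels <- sim$metadata$diagnosis
  set.seed(44)
  perm <- sample(seq_along(labels))
  pv1 <- permanova(d, labels, permutations = 4999, seed = 5)
  pv2 <- permanova(d[perm, perm], labels[perm], permutations = 4999, seed = 5)
  expect_equal(pv1$pseudo_f, pv2$pseudo_f, tolerance = 1e-12)
  expect_lt(abs(pv1$p - pv2$p), 0.03)
})

test_that("pairwise PERMANOVA mirrors restricted submatrix runs", {
  sim <- simulate_cohort(cohort_config(), seed = 16)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  labels <- sim$metadata$diagnosis
  pw <- pairwise_permanova(d, labels, permutations = 99, seed = 4)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$q >= pw$p - 1e-12))
  keep <- labels %in% c("Normal", "CCU")
  direct <- permanova(d[keep, keep], labels[keep], permutations = 99,
                      seed = 7)
  row <- dplyr::filter(pw, group1 == "Normal", group2 == "CCU")
  expect_equal(row$pseudo_f, direct$pseudo_f, tolerance = 1e-12)
})

test_that("PERMDISP dispersions match betadisper centroids; degenerate flagged", {
  sim <- simulate_cohort(cohort_config(), seed = 17)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  dp <- permdisp(d, sim$metadata$diagnosis, permutations = 99, seed = 1)
  bd <- vegan::betadisper(as.dist(d), sim$metadata$diagnosis,
                          type = "centroid")
  ref <- tapply(bd$distances, sim$metadata$diagnosis, mean)
  expect_equal(dp$dispersion$mean_dispersion,
               as.numeric(ref[dp$dispersion$group]), tolerance = 1e-6)
  expect_false(dp$degenerate)

  # duplicated identical points: zero dispersion everywhere
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 1), c(9, 1))
  ddeg <- as.matrix(dist(x))
  rownames(ddeg) <- colnames(ddeg) <- paste0("S", 1:6)
  expect_warning(
    dpd <- permdisp(ddeg, rep(c("a", "b", "c"), each = 2),
                    permutations = 49, seed = 1),
    "degenerate")
  expect_true(dpd$degenerate)
  expect_equal(dpd$dispersion$mean_dispersion, rep(0, 3))
})

test_that("low-concentration groups are more dispersed", {
  cfg <- cohort_config(group_sizes = c(Normal = 15, CCU = 15),
                       concentrations = c(Normal = 50, CCU = 5))
  sim <- simulate_cohort(cfg, seed = 18)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  dp <- permdisp(d, sim$metadata$diagnosis, permutations = 99, seed = 1)
  disp <- setNames(dp$dispersion$mean_dispersion, dp$dispersion$group)
  expect_gt(disp[["CCU"]], disp[["Normal"]])
})

test_that("PERMDISP holds its size on null data", {
  cfg <- null_two_group_config(n_per_group = 10, n_genera = 10)
  rejections <- 0L
  for (r in 1:200) {
    sim <- simulate_cohort(cfg, seed = 20000 + r)
    d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                        "counts")))
    dp <- permdisp(d, sim$metadata$diagnosis, permutations = 99,
                   seed = r)
    if (dp$p <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("host factor screen tests each factor independently", {
  sim <- simulate_cohort(cohort_config(), seed = 19)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  meta <- sim$metadata
  meta$mirror <- meta$diagnosis
  set.seed(55)
  meta$noise <- sample(c("lo", "hi"), nrow(meta), replace = TRUE)
  meta$single <- "same"
  expect_warning(
    scr <- host_factor_screen(d, meta, c("mirror", "noise", "single"),
                              permutations = 99, seed = 2),
    "fewer than two usable levels")
  expect_equal(nrow(scr), 2)
  global <- permanova(d, meta$diagnosis, permutations = 99, seed = 3)
  expect_equal(scr$pseudo_f[scr$factor == "mirror"], global$pseudo_f,
               tolerance = 1e-12)
  expect_equal(scr$p, sort(scr$p))

  # a factor unrelated to structure should rarely look significant
  set.seed(77)
  sig <- 0L
  for (r in 1:100) {
    meta$shuffled <- sample(meta$noise)
    s <- host_factor_screen(d, meta, "shuffled", permutations = 99,
                            seed = 100 + r)
    if (s$p <= 0.05) sig <- sig + 1L
  }
  expect_gte(100 - sig, 90)
})

test_that("host factor screen handles a wide factor panel", {
  sim <- simulate_cohort(cohort_config(), seed = 23)
  d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                      "counts")))
  meta <- sim$metadata
  set.seed(66)
  factors <- sprintf("f%02d", 1:27)
  for (f in factors) {
    meta[[f]] <- sample(c("a", "b", "c"), nrow(meta), replace = TRUE)
  }
  scr <- host_factor_screen(d, meta, factors, permutations = 99, seed = 9)
  expect_equal(nrow(scr), 27)
  expect_setequal(scr$factor, factors)
})
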