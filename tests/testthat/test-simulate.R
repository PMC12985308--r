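test_that("default profiles carry the published group means and prevalences", {
  prof <- default_group_profiles()
  lac <- dplyr::filter(prof, genus == "Lactobacillus")
  expect_equal(lac$mean_ra[lac$group == "Normal"], 0.9058)
  expect_equal(lac$mean_ra[lac$group == "CCU"], 0.1952)
  fanny <- dplyr::filter(prof, genus == "Fannyhessea", group == "Normal")
  expect_equal(fanny$prevalence, 0)
  expect_equal(fanny$mean_ra, 0)
  # the filler genus closes every group's composition exactly
  sums <- tapply(prof$mean_ra, prof$group, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  expect_true(all(prof$prevalence >= 0 & prof$prevalence <= 1))
  expect_true(all(prof$prevalence[prof$mean_ra > 0] > 0))
})

test_that("simulation is seed-deterministic and respects count invariants", {
  cfg <- cohort_config()
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$metadata, b$metadata)
  c <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$abundance, c$abundance))

  mat <- as.matrix(a$abundance[, -1])
  expect_true(all(mat >= 0))
  expect_true(all(mat == round(mat)))
  expect_true(all(rowSums(mat) >= 100))
  expect_equal(nrow(mat), sum(cohort_config()$group_sizes))
  expect_equal(table(a$metadata$diagnosis)[diagnosis_levels()],
               table(factor(rep(diagnosis_levels(), c(25, 23, 24, 10)),
                            levels = diagnosis_levels())))
})

test_that("zero-prevalence genera never appear in their group", {
  sim <- simulate_cohort(cohort_config(), seed = 11)
  normal_ids <- sim$metadata$sample_id[sim$metadata$diagnosis == "Normal"]
  sub <- sim$abundance[sim$abundance$sample_id %in% normal_ids, ]
  expect_true(all(sub$Fannyhessea == 0))
  expect_true(all(sub$Pasteurella == 0))
})

test_that("empirical means converge to configured means (law of large numbers)", {
  n_genera <- 6
  m <- c(0.5, 0.2, 0.15, 0.1, 0.04, 0.01)
  prof <- make_profiles("Normal", paste0("G", 1:n_genera), list(m),
                        list(rep(1, n_genera)))
  cfg <- cohort_config(group_sizes = c(Normal = 1000),
                       concentrations = c(Normal = 500),
                       lib_meanlog = log(20000), lib_sdlog = 0.2,
                       profiles = prof)
  sim <- simulate_cohort(cfg, seed = 3)
  mat <- as.matrix(sim$abundance[, -1])
  emp <- colMeans(mat / rowSums(mat))
  expect_true(all(abs(emp - m) < 0.01))
})

test_that("empirical prevalence converges to configured prevalence", {
  pi_g <- c(1, 0.7, 0.3, 0.05)
  m <- c(0.7, 0.15, 0.1, 0.05)
  prof <- make_profiles("Normal", paste0("G", 1:4), list(m), list(pi_g))
  cfg <- cohort_config(group_sizes = c(Normal = 2000),
                       concentrations = c(Normal = 50),
                       lib_meanlog = log(10000), lib_sdlog = 0.2,
                       profiles = prof)
  sim <- simulate_cohort(cfg, seed = 5)
  mat <- as.matrix(sim$abundance[, -1])
  expect_true(all(abs(colMeans(mat > 0) - pi_g) < 0.03))
})

test_that("within-group dispersion decreases with Dirichlet concentration", {
  mean_disp <- function(concentration, seed) {
    m <- c(0.6, 0.2, 0.1, 0.05, 0.05)
    prof <- make_profiles("Normal", paste0("G", 1:5), list(m),
                          list(rep(1, 5)))
    cfg <- cohort_config(group_sizes = c(Normal = 40),
                         concentrations = c(Normal = concentration),
                         profiles = prof)
    sim <- simulate_cohort(cfg, seed = seed)
    d <- aitchison_distance(clr_transform(replace_zeros(sim$abundance,
                                                        "counts")))
    mean(d[upper.tri(d)])
  }
  expect_gt(mean_disp(5, seed = 2), mean_disp(50, seed = 2))
})

test_that("an all-absent draw is re-drawn with Lactobacillus forced present", {
  prof <- make_profiles("Normal", c("Lactobacillus", "Prevotella"),
                        list(c(0.9, 0.1)), list(c(0.01, 0.01)))
  cfg <- cohort_config(group_sizes = c(Normal = 6),
                       concentrations = c(Normal = 20), profiles = prof)
  expect_warning(sim <- simulate_cohort(cfg, seed = 1),
                 "forced present")
  expect_true(all(rowSums(as.matrix(sim$abundance[, -1])) >= 100))
})

test_that("invalid configurations are rejected", {
  prof <- make_profiles("Normal", c("A", "B"), list(c(0.5, 0.5)),
                        list(c(1, 1)))
  expect_error(cohort_config(group_sizes = c(Normal = 0), profiles = prof),
               ">= 1")
  bad <- make_profiles("Normal", c("A", "B"), list(c(0.5, 0.5)),
                       list(c(1, 0)))
  expect_error(cohort_config(group_sizes = c(Normal = 5),
                             concentrations = c(Normal = 10),
                             profiles = bad),
               "zero prevalence")
  over <- make_profiles("Normal", c("A", "B"), list(c(0.8, 0.5)),
                        list(c(1, 1)))
  expect_error(cohort_config(group_sizes = c(Normal = 5),
                             concentrations = c(Normal = 10),
                             profiles = over),
               "at most 1")
})
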