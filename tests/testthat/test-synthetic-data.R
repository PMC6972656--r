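# The synthetic-data generators: planted moments, determinism, and the
# consistency of the density-ratio estimator of the expressing fraction.

test_that("truth table enforces its invariants", {
  expect_error(truth_table(c("a", "a")), "unique")
  expect_error(truth_table("a", mean_expression = 0), "mean_expression")
  expect_error(truth_table("a", dispersion = -1), "dispersion")
  expect_error(truth_table("a", expressing_fraction = 1.6), "\\[0, 1.5\\]")
  expect_error(truth_table("a", expressing_fraction = 0.3,
                           pattern_class = "absent"), "absent")
  tt <- truth_table(c("a", "b", "c"),
                    expressing_fraction = c(0.001, 0.3, 1.2))
  expect_identical(tt$pattern_class, c("absent", "mosaic", "widespread"))
})

test_that("sim_config rejects inconsistent intensity ordering", {
  expect_error(sim_config(expressing_intensity = 0.5), "expressing_intensity")
  expect_error(sim_config(n_replicates_per_group = 1), ">= 2")
})

test_that("NB counts reproduce the planted moments", {
  # large-mean Poisson limit: empirical log2 ratio within +/- 0.01 of 1
  tt <- truth_table("g", planted_log2fc = 1, mean_expression = 1e6,
                    dispersion = 0)
  cfg <- sim_config(seed = 101, library_size_range = c(1, 1))
  cm <- simulate_counts(tt, cfg)
  grp <- cm$samples$group
  lr <- log2(mean(cm$counts[1, grp == "GABA_IP"]) /
               mean(cm$counts[1, grp == "DA_IP"]))
  expect_lt(abs(lr - 1), 0.01)

  # mean 100, dispersion 0.1: variance within 3 MC SE of 1,100 at 1e4 draws
  tt2 <- truth_table(paste0("g", 1:2500), planted_log2fc = 0,
                     mean_expression = 100, dispersion = 0.1)
  cm2 <- simulate_counts(tt2, sim_config(seed = 102,
                                         library_size_range = c(1, 1),
                                         n_replicates_per_group = 2))
  draws <- as.numeric(cm2$counts)   # 10,000 iid NB(mu = 100, a = 0.1) draws
  true_var <- 100 + 0.1 * 100^2
  # MC standard error of a sample variance: sqrt((mu4 - var^2) / n)
  mu <- 100; a <- 0.1
  mu4 <- mean((stats::rnbinom(2e5, mu = mu, size = 1 / a) - mu)^4)
  se_var <- sqrt((mu4 - true_var^2) / length(draws))
  expect_lt(abs(stats::var(draws) - true_var), 3 * se_var)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(true_var / length(draws)))
})

test_that("null planting gives symmetric group means", {
  tt <- truth_table(paste0("g", 1:2000), planted_log2fc = 0,
                    mean_expression = 100, dispersion = 0.05)
  cm <- simulate_counts(tt, sim_config(seed = 103))
  sf <- cm$true_size_factors
  y <- sweep(cm$counts, 2, sf, "/")
  grp <- cm$samples$group
  d <- rowMeans(y[, grp == "GABA_IP"]) - rowMeans(y[, grp == "DA_IP"])
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(nrow(y)))
})

test_that("generators are bit-identical for a fixed seed", {
  tt <- truth_table(paste0("g", 1:20), planted_log2fc = 0,
                    categories = list("receptors"))
  cfg <- sim_config(seed = 104, grid_shape = c(10, 10, 8))
  a <- simulate_inputs(tt, cfg)
  b <- simulate_inputs(tt, cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$grids, b$grids)
  expect_identical(a$annotations, b$annotations)
  ct1 <- simulate_cell_table(0.4, 0.1, 50, 3, 0.35, seed = 104)
  ct2 <- simulate_cell_table(0.4, 0.1, 50, 3, 0.35, seed = 104)
  expect_identical(ct1, ct2)
})

test_that("expression grids realize the planted voxel probabilities", {
  cfg <- sim_config(seed = 105)   # default mask: 10,816 voxels
  # reference gene alone: density within 3 binomial SE of 0.2
  tt_ref <- truth_table("Vgat", expressing_fraction = 1)
  sim <- simulate_expression_grids(tt_ref, cfg)
  n_vox <- sum(sim$mask$labels == 1L)
  expect_gt(n_vox, 1e4)
  d_ref <- compute_density(sim$grids[["Vgat"]][[1]], sim$mask,
                           cfg$detection_threshold)
  se <- sqrt(0.2 * 0.8 / n_vox)
  expect_lt(abs(d_ref - 0.2), 3 * se)

  # zero expressing fraction: density exactly 0
  tt0 <- truth_table("off", expressing_fraction = 0)
  sim0 <- simulate_expression_grids(tt0, cfg)
  expect_identical(compute_density(sim0$grids[["off"]][[1]], sim0$mask,
                                   cfg$detection_threshold), 0)

  # density ratio estimates the expressing fraction (ratio-of-binomials SE)
  tt3 <- truth_table(c("g", "Vgat"), expressing_fraction = c(0.3, 1))
  sim3 <- simulate_expression_grids(tt3, cfg)
  s <- summarize_ish(sim3$grids, sim3$mask, cfg$detection_threshold)
  fr <- population_fractions(s, "Vgat")
  p_g <- 0.3 * 0.2; p_r <- 0.2
  se_ratio <- 0.3 * sqrt((1 - p_g) / (p_g * n_vox) +
                           (1 - p_r) / (p_r * n_vox))
  expect_lt(abs(fr$fraction - 0.3), 3 * se_ratio)
})

test_that("density-ratio error shrinks with mask size (consistency)", {
  tt <- truth_table(c("g", "Vgat"), expressing_fraction = c(0.4, 1))
  err <- vapply(list(c(12, 12, 9), c(40, 40, 26)), function(shape) {
    cfg <- sim_config(seed = 106, grid_shape = shape)
    reps <- vapply(0:9, function(k) {
      cfg$seed <- 106L + k
      sim <- simulate_expression_grids(tt, cfg)
      s <- summarize_ish(sim$grids, sim$mask, cfg$detection_threshold)
      population_fractions(s, "Vgat")$fraction
    }, numeric(1))
    sqrt(mean((reps - 0.4)^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("expressing probabilities above 1 are clipped with a warning", {
  tt <- truth_table("hot", expressing_fraction = 1.4)
  cfg <- sim_config(seed = 107, reference_expressing_probability = 0.9,
                    grid_shape = c(10, 10, 8))
  expect_warning(sim <- simulate_expression_grids(tt, cfg), "clipped")
  prov <- attr(sim$grids[["hot"]][[1]], "provenance")
  expect_true(prov$clipped)
  expect_identical(prov$expressing_probability, 1)
})

test_that("cell tables follow the configured class-conditional model", {
  # degenerate probabilities: every candidate+ cell is HA+
  ct <- simulate_cell_table(1, 0, 200, 2, gaba_proportion = 0.4, seed = 108)
  expect_true(all(ct$ha[ct$candidate]))
  # no GABA cells at all
  ct0 <- simulate_cell_table(0.5, 0.5, 200, 2, gaba_proportion = 0,
                             seed = 108)
  expect_identical(sum(ct0$ha), 0L)
  # binomial oracle on P(candidate | HA+)
  ct2 <- simulate_cell_table(0.4, 0.05, 500, 3, gaba_proportion = 0.5,
                             double_positive_rate = 0, seed = 109)
  for (a in unique(ct2$animal_id)) {
    d <- ct2[ct2$animal_id == a & ct2$ha, ]
    se <- sqrt(0.4 * 0.6 / nrow(d))
    expect_lt(abs(mean(d$candidate) - 0.4), 3 * se)
  }
  # multinomial class frequencies within 3 SE
  n <- nrow(ct2)
  p_ha <- 0.5
  expect_lt(abs(mean(ct2$ha) - p_ha), 3 * sqrt(p_ha * (1 - p_ha) / n))
  expect_error(simulate_cell_table(1.2, 0, 10, 1, 0.5), "\\[0, 1\\]")
})

test_that("annotations copy truth and add distractors at the planted rate", {
  tt <- truth_table("g1", categories = list("receptors"))
  ann <- simulate_annotations(tt, distractor_rate = 0, seed = 110)
  expect_identical(ann$categories[[1]], "receptors")
  expect_identical(ann$pattern_flag, tt$pattern_class)

  tt0 <- truth_table("g1")
  ann0 <- simulate_annotations(tt0, distractor_rate = 0, seed = 110)
  expect_length(ann0$categories[[1]], 0)

  tt_many <- truth_table(paste0("g", 1:1000))
  ann_many <- simulate_annotations(tt_many, distractor_rate = 0.1,
                                   seed = 111)
  n_extra <- sum(lengths(ann_many$categories))
  n_trials <- 1000 * length(default_categories())
  se <- sqrt(n_trials * 0.1 * 0.9)
  expect_lt(abs(n_extra - n_trials * 0.1), 3 * se)
})

test_that("clustered grids keep the marginal expressing fraction", {
  tt <- truth_table(c("g", "Vgat"), expressing_fraction = c(0.3, 1))
  cfg <- sim_config(seed = 112)
  sim <- simulate_expression_grids(tt, cfg, clustered = TRUE)
  d <- compute_density(sim$grids[["g"]][[1]], sim$mask,
                       cfg$detection_threshold)
  expect_lt(abs(d - 0.3 * 0.2), 0.005)  # blob growth targets the count
})
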