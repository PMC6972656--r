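# Differential enrichment: size factors, the NB Wald fit, BH adjustment,
# the three-way call, RPKM z-scores and the marker-panel gate.

test_that("size factors match forced and brute-force oracles", {
  # identical samples -> all factors 1
  m <- matrix(rep(c(5L, 9L, 20L), 4), 3)
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # sample B = 2 x sample A gene-wise -> (1/sqrt(2), sqrt(2))
  m2 <- cbind(a = c(10L, 30L), b = c(20L, 60L))
  rownames(m2) <- c("g1", "g2")
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # random matrices vs the O(genes x samples) loop
  set.seed(201)
  for (i in 1:20) {
    m3 <- matrix(rpois(50 * 6, 30) + sample(0:1, 300, replace = TRUE),
                 50, 6, dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
    expect_equal(unname(estimate_size_factors(m3)), size_factor_oracle(m3))
  }

  # all-zero-containing genes: no valid reference gene -> explicit error
  m4 <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("g1", "g2"), NULL))
  expect_error(estimate_size_factors(m4), "pseudo-reference")
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(202)
  m <- matrix(rnbinom(80 * 6, mu = 50, size = 5), 80, 6,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:6)))
  # DESeq2 medians log-ratios (geometric middle-pair average at even gene
  # counts) where this package medians the ratios themselves; the two
  # definitions agree exactly at odd counts and to ~1e-3 otherwise.
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 2e-3)
  m_odd <- m[1:79, ]
  expect_equal(unname(estimate_size_factors(m_odd)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m_odd)),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the from-definition step-up oracle", {
  expect_equal(adjust_bh(0.03), 0.03)                 # m = 1 identity
  expect_equal(adjust_bh(rep(0.01, 10)), rep(0.01, 10))  # ties at rank m
  set.seed(203)
  for (i in 1:100) {
    p <- runif(200)^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # elementwise dominance and monotonicity on sorted input
  p <- sort(runif(50))
  a <- adjust_bh(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a) >= 0))
})

test_that("enrichment calls follow the inclusive significance rule", {
  tab <- candidate_table()
  expect_identical(call_enriched(tab$log2fc, tab$p_adj),
                   rep("enriched", nrow(tab)))
  expect_identical(call_enriched(1, 0.05), "enriched")   # boundary inclusive
  expect_identical(call_enriched(-2, 0.04), "de_enriched")
  expect_identical(call_enriched(0.5, 0.051), "not_significant")
})

test_that("the NB Wald fit is sane on null and planted data", {
  # identical counts in every sample: log2fc 0, p ~ 1
  m <- tiny_counts(matrix(7L, 5, 6, dimnames = list(paste0("g", 1:5), NULL)))
  fit <- nb_enrichment(m)
  expect_equal(fit$results$log2fc, rep(0, 5))
  expect_true(all(fit$results$p_raw > 0.99))

  # planted enrichment is recovered with small bias
  tt <- truth_table(paste0("g", 1:400),
                    planted_log2fc = c(rep(1.5, 40), rep(0, 360)),
                    mean_expression = 150, dispersion = 0.08)
  cm <- simulate_counts(tt, sim_config(seed = 204))
  fit2 <- nb_enrichment(cm)
  planted <- fit2$results[1:40, ]
  expect_gte(mean(planted$call == "enriched"), 0.9)
  expect_lte(abs(mean(planted$log2fc) - 1.5), 0.1)
})

test_that("Wald p agrees with a Poisson likelihood-ratio oracle at moderate effects", {
  lrt_oracle <- function(a, b) {
    d <- data.frame(y = c(a, b), g = rep(c("A", "B"), each = length(a)))
    m1 <- stats::glm(y ~ g, family = stats::poisson, data = d)
    m0 <- stats::glm(y ~ 1, family = stats::poisson, data = d)
    stats::pchisq(stats::anova(m0, m1)$Deviance[2], 1, lower.tail = FALSE)
  }
  fit_p <- function(a, b) {
    cm <- tiny_counts(matrix(c(a, b), 1,
                             dimnames = list("g", paste0("s", 1:6))))
    nb_enrichment(cm, size_factors = stats::setNames(rep(1, 6),
                                                     paste0("s", 1:6)))$results$p_raw
  }
  p_wald <- fit_p(c(10L, 12L, 11L), c(16L, 18L, 17L))
  p_lrt <- lrt_oracle(c(10, 12, 11), c(16, 18, 17))
  expect_lt(abs(p_wald / p_lrt - 1), 0.10)

  # at an extreme separation both routes agree the effect is overwhelming,
  # though their tail areas diverge (Wald vs LRT)
  expect_lt(fit_p(c(5L, 6L, 7L), c(50L, 60L, 70L)), 1e-10)
  expect_lt(lrt_oracle(c(5, 6, 7), c(50, 60, 70)), 1e-10)
})

test_that("results are invariant under sample permutation", {
  tt <- truth_table(paste0("g", 1:50), planted_log2fc = 0.5)
  cm <- simulate_counts(tt, sim_config(seed = 205))
  fit <- nb_enrichment(cm)
  perm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[, perm], cm$samples$group[perm])
  fit2 <- nb_enrichment(cm2)
  expect_equal(fit$results, fit2$results)
})

test_that("RPKM and z-scores follow their definitions", {
  counts <- matrix(c(100L, 100L, 50L, 100L, 200L, 100L), 3,
                   dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  counts["g1", ] <- c(100L, 100L)
  m <- count_matrix(counts, c("GABA_IP", "DA_IP"),
                    gene_length_kb = c(g1 = 1, g2 = 2, g3 = 0.5))
  # unit case: count 100, 1 kb, 1e6 total reads -> RPKM 100
  m$counts["g1", "a"] <- 100L
  tot <- colSums(m$counts)
  z <- compute_rpkm_zscore(m)
  rpkm <- attr(z, "rpkm")
  expect_equal(rpkm["g1", "a"], 100 / (1 * tot[["a"]] / 1e6))
  # doubling every count of one sample leaves its RPKM unchanged
  m2 <- m; m2$counts[, "b"] <- m$counts[, "b"] * 2L
  expect_equal(attr(compute_rpkm_zscore(m2), "rpkm")[, "b"], rpkm[, "b"])
  # every non-constant row has mean 0, sd 1
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  sds <- apply(z, 1, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-12))
  # missing length -> dropped with warning
  m3 <- m; m3$gene_length_kb <- c(g1 = 1, g2 = 2)
  expect_warning(z3 <- compute_rpkm_zscore(m3), "dropped")
  expect_false("g3" %in% rownames(z3))
})

test_that("marker-panel validation passes, and fails on swapped labels", {
  gaba <- c("Slc32a1", "Gad1", "Gad2", "Gabra1", "Pvalb")
  da <- c("Dat", "Th", "Aadc")
  others <- paste0("g", 1:40)
  tt <- truth_table(c(gaba, da, others),
                    planted_log2fc = c(rep(2, 5), rep(0, 3), rep(0, 40)),
                    mean_expression = 200, dispersion = 0.05)
  cm <- simulate_counts(tt, sim_config(seed = 206))
  fit <- nb_enrichment(cm)
  panel <- validate_marker_panel(fit, gaba, da)
  expect_true(attr(panel, "pass"))

  swapped <- count_matrix(cm$counts,
                          ifelse(cm$samples$group == "GABA_IP",
                                 "DA_IP", "GABA_IP"))
  panel2 <- validate_marker_panel(nb_enrichment(swapped), gaba, da)
  expect_false(attr(panel2, "pass"))

  # a planted-enriched DA marker is named in the failure
  tt3 <- tt; tt3$planted_log2fc[tt3$gene_id == "Th"] <- 2
  class(tt3) <- class(tt)
  panel3 <- validate_marker_panel(nb_enrichment(
    simulate_counts(tt3, sim_config(seed = 207))), gaba, da)
  expect_false(attr(panel3, "pass"))
  expect_false(panel3$ok[panel3$marker == "Th"])
  # missing marker -> overall fail
  panel4 <- validate_marker_panel(fit, c(gaba, "NotAGene"), da)
  expect_false(attr(panel4, "pass"))
  expect_identical(panel4$status[panel4$marker == "NotAGene"], "missing")
})

test_that("count matrix and DE results round-trip through TSV", {
  tt <- truth_table(paste0("g", 1:30), planted_log2fc = 1)
  cm <- simulate_counts(tt, sim_config(seed = 208))
  d <- withr::local_tempdir()
  write_count_matrix(cm, file.path(d, "counts.tsv"),
                     file.path(d, "samples.tsv"),
                     file.path(d, "lengths.tsv"))
  cm2 <- read_count_matrix(file.path(d, "counts.tsv"),
                           file.path(d, "samples.tsv"),
                           file.path(d, "lengths.tsv"))
  expect_equal(unname(cm2$counts), unname(cm$counts))
  fit <- nb_enrichment(cm)
  write_de_results(fit, file.path(d, "de.tsv"))
  back <- read_de_results(file.path(d, "de.tsv"))
  expect_equal(back$p_adj, fit$results$p_adj, tolerance = 1e-12)
  expect_identical(back$call, fit$results$call)
})
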