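# Shared fixtures built in code.

# A small count matrix with known structure.
tiny_counts <- function(counts, n_per_group = 3) {
  count_matrix(counts, rep(c("GABA_IP", "DA_IP"), each = n_per_group))
}

# Truth table for the deterministic end-to-end regime: strong planted
# enrichment, expressing fractions well inside / outside the 5-50% window,
# annotations without distractors. Gives exact planted-candidate recovery
# on the default 10,816-voxel mask with 3 replicate grids.
deterministic_truth <- function() {
  cand_frac <- c(0.10, 0.20, 0.30, 0.40, 0.45,
                 0.15, 0.25, 0.35, 0.12, 0.22, 0.32, 0.42)
  # log2fc 3 at dispersion 0.05 puts every planted effect ~11 Wald SEs
  # from the null: the enrichment stage is effectively deterministic.
  cand <- truth_table(sprintf("cand%02d", seq_along(cand_frac)),
                      planted_log2fc = 3, dispersion = 0.05,
                      expressing_fraction = cand_frac,
                      categories = list("receptors"), cre_available = TRUE)
  outwin <- truth_table(paste0("outwin", 1:4), planted_log2fc = 3,
                        dispersion = 0.05,
                        expressing_fraction = c(0.02, 0.80, 1.20, 1.20),
                        categories = list("transporters"),
                        cre_available = TRUE)
  nocre <- truth_table(paste0("nocre", 1:3), planted_log2fc = 3,
                       dispersion = 0.05,
                       expressing_fraction = c(0.2, 0.3, 0.4),
                       categories = list("receptors"), cre_available = FALSE)
  spread <- truth_table(paste0("spread", 1:2), planted_log2fc = 3,
                        dispersion = 0.05, expressing_fraction = 0.3,
                        pattern_class = "widespread",
                        categories = list("receptors"), cre_available = TRUE)
  excl <- truth_table(c("Gata3", "Nts"), planted_log2fc = 3,
                      dispersion = 0.05,
                      expressing_fraction = c(0.3, 0.2),
                      categories = list("transcription factors"),
                      cre_available = TRUE)
  null <- truth_table(paste0("null", 1:60), planted_log2fc = 0,
                      dispersion = 0.05,
                      expressing_fraction = 0.2, cre_available = FALSE)
  out <- rbind(cand, outwin, nocre, spread, excl, null)
  class(out) <- c("truth_table", "data.frame")
  out
}

deterministic_candidates <- function() sprintf("cand%02d", 1:12)

# Independent from-definition BH step-up (O(m log m), no p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- min(running, 1)
  }
  adj
}

# Brute-force median-of-ratios loop.
size_factor_oracle <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  ok <- apply(counts, 1, function(r) all(r > 0))
  vapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[ok, j] / geo[ok])
  }, numeric(1))
}

# Explicit voxel-loop density / intensity oracles.
density_oracle <- function(grid, mask, threshold) {
  n_in <- 0L; n_expr <- 0L
  for (i in seq_along(mask$labels)) {
    if (mask$labels[i] == mask$region_id) {
      n_in <- n_in + 1L
      if (grid[i] > threshold) n_expr <- n_expr + 1L
    }
  }
  n_expr / n_in
}

intensity_oracle <- function(grid, mask, threshold) {
  s <- 0; n <- 0L
  for (i in seq_along(mask$labels)) {
    if (mask$labels[i] == mask$region_id && grid[i] > threshold) {
      s <- s + grid[i]; n <- n + 1L
    }
  }
  if (n == 0L) NA_real_ else s / n
}

random_grid_and_mask <- function(shape = c(8, 8, 6)) {
  vals <- array(stats::rexp(prod(shape)), dim = shape)
  lab <- array(sample(0:1, prod(shape), replace = TRUE), dim = shape)
  if (!any(lab == 1L)) lab[1] <- 1L
  list(grid = expression_grid(vals, "g"), mask = region_mask(lab, 1L))
}
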