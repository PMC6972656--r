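#' Construct a count matrix with sample groups
#'
#' Container for a gene x sample matrix of non-negative integer read
#' counts from two immunoprecipitated populations, with an optional
#' gene-length vector used only for RPKM.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param group character/factor of length `ncol(counts)` with exactly two
#'   levels (conventionally `"GABA_IP"` and `"DA_IP"`).
#' @param gene_length_kb optional named numeric vector of transcript
#'   lengths in kilobases.
#' @return list of class `"count_matrix"` with elements `counts`,
#'   `samples` (data.frame: sample_id, group, replicate) and
#'   `gene_length_kb`.
#' @export
count_matrix <- function(counts, group, gene_length_kb = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop("group must have one entry per sample")
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 1L)) stop("both groups must be non-empty")
  replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  samples <- data.frame(sample_id = colnames(counts), group = group,
                        replicate = replicate, stringsAsFactors = FALSE)
  if (!is.null(gene_length_kb)) {
    if (is.null(names(gene_length_kb)))
      stop("gene_length_kb must be named by gene id")
    if (any(gene_length_kb <= 0)) stop("gene lengths must be positive")
  }
  structure(list(counts = counts, samples = samples,
                 gene_length_kb = gene_length_kb),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' Classical median-of-ratios normalization: each gene with strictly
#' positive counts in every sample contributes the ratio of its count to
#' its across-sample geometric mean; a sample's size factor is the median
#' of those ratios. Genes with any zero count are excluded from the
#' median.
#'
#' @param m a [count_matrix()] or a bare counts matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' cm <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' estimate_size_factors(cm)   # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep))
    stop("no gene has positive counts in every sample; ",
         "median-of-ratios is undefined (a pseudo-reference fallback is ",
         "not applied silently)")
  lc <- log(counts[keep, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(exp(lc - loggeo), 2, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial differential enrichment between two IP populations
#'
#' Fits the package's simplified negative-binomial Wald test per gene:
#' median-of-ratios size factors, method-of-moments gene-wise dispersion on
#' normalized counts moderated toward a pooled across-gene moment estimate,
#' a pseudocounted log2 fold change of group means, a Wald statistic from
#' the NB variance model `mu + a * mu^2`, two-sided p-values from the
#' normal reference, Benjamini-Hochberg adjustment, and a three-way call
#' (enriched / de-enriched / not significant) at `p_adj <= alpha`
#' (inclusive).
#'
#' The moderation (weights: residual df of the gene against `prior_df` for
#' the pooled estimate) exists because raw gene-wise moment dispersions at
#' three replicates per group make the Wald test strongly anticonservative;
#' set `prior_df = 0` for the raw gene-wise estimator.
#'
#' @param m a [count_matrix()].
#' @param numerator,denominator the group labels forming the fold change
#'   `log2(numerator / denominator)`; defaults: `"GABA_IP"` over `"DA_IP"`
#'   when present, else second over first sorted label.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param pseudocount added to each group's normalized mean before the log
#'   ratio (default 0.5).
#' @param prior_df prior degrees of freedom pulling gene-wise dispersions
#'   toward the pooled estimate (default 50).
#' @param dispersion_floor lower bound on dispersions (default 1e-8).
#' @param size_factors optional externally supplied size factors.
#' @return object of class `"nb_enrichment"`: list with `results` (a
#'   data.frame: gene_id, base_mean, log2fc, se_log2fc, p_raw, p_adj,
#'   call), `size_factors`, `dispersions` (gene_wise, moderated, pooled),
#'   `alpha`, and the contrast labels. Methods: `print`, `summary`,
#'   `coef`, `plot`.
#' @examples
#' tt <- truth_table(paste0("g", 1:50),
#'                   planted_log2fc = c(rep(2, 5), rep(0, 45)))
#' fit <- nb_enrichment(simulate_counts(tt, sim_config(seed = 4)))
#' head(summary(fit)$results)
#' @export
nb_enrichment <- function(m, numerator = NULL, denominator = NULL,
                          alpha = 0.05, pseudocount = 0.5, prior_df = 50,
                          dispersion_floor = 1e-8, size_factors = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  grp <- m$samples$group
  lev <- sort(unique(grp))
  if (is.null(numerator))
    numerator <- if ("GABA_IP" %in% lev) "GABA_IP" else lev[2]
  if (is.null(denominator)) denominator <- setdiff(lev, numerator)[1]
  if (!all(c(numerator, denominator) %in% lev))
    stop("numerator/denominator must match the sample groups")
  if (sum(grp == numerator) < 2L || sum(grp == denominator) < 2L)
    stop("at least two samples per group are required")

  sf <- if (is.null(size_factors)) estimate_size_factors(m) else size_factors
  if (any(sf <= 0)) stop("size factors must be positive")
  y <- sweep(m$counts, 2, sf, "/")

  iA <- which(grp == numerator)
  iB <- which(grp == denominator)
  nA <- length(iA); nB <- length(iB)
  mA <- rowMeans(y[, iA, drop = FALSE])
  mB <- rowMeans(y[, iB, drop = FALSE])
  vA <- apply(y[, iA, drop = FALSE], 1, stats::var)
  vB <- apply(y[, iB, drop = FALSE], 1, stats::var)

  base_mean <- rowMeans(y)
  mu0 <- (mA + mB) / 2
  s2 <- (vA + vB) / 2                       # pooled within-group variance
  pos <- mu0 > 0
  disp_gene <- rep(dispersion_floor, nrow(y))
  disp_gene[pos] <- pmax((s2[pos] - mu0[pos]) / mu0[pos]^2, dispersion_floor)
  disp_pooled <- max(sum(s2[pos] - mu0[pos]) / sum(mu0[pos]^2),
                     dispersion_floor)
  df_gene <- (nA - 1) + (nB - 1)
  disp <- (df_gene * disp_gene + prior_df * disp_pooled) /
    (df_gene + prior_df)

  log2fc <- log2((mA + pseudocount) / (mB + pseudocount))

  # NB variance of a group mean of normalized counts:
  # mean_j (mu / s_j + a mu^2) / n; delta method on log2 of the mean
  invA <- mean(1 / sf[iA]); invB <- mean(1 / sf[iB])
  varMA <- (mA * invA + disp * mA^2) / nA
  varMB <- (mB * invB + disp * mB^2) / nB
  se <- sqrt(varMA / (mA + pseudocount)^2 + varMB / (mB + pseudocount)^2) /
    log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- adjust_bh(p_raw)
  call <- call_enriched(log2fc, p_adj, alpha = alpha)

  res <- data.frame(gene_id = rownames(m$counts), base_mean = base_mean,
                    log2fc = log2fc, se_log2fc = se, p_raw = p_raw,
                    p_adj = p_adj, call = call, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(results = res, size_factors = sf,
                 dispersions = data.frame(gene_id = res$gene_id,
                                          gene_wise = disp_gene,
                                          moderated = disp,
                                          row.names = NULL),
                 pooled_dispersion = disp_pooled,
                 alpha = alpha, numerator = numerator,
                 denominator = denominator,
                 pseudocount = pseudocount, prior_df = prior_df,
                 n_samples = c(nA, nB)),
            class = "nb_enrichment")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone), preserving input
#' order. Thin validating wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as enriched, de-enriched or not significant
#'
#' A gene is enriched when its adjusted p-value is `alpha` or less
#' (inclusive) and its log2 fold change positive; de-enriched with a
#' negative fold change; not significant otherwise.
#'
#' @param log2fc,p_adj numeric vectors of equal length.
#' @param alpha significance level (default 0.05).
#' @return character vector in
#'   `{"enriched", "de_enriched", "not_significant"}`.
#' @export
call_enriched <- function(log2fc, p_adj, alpha = 0.05) {
  stopifnot(length(log2fc) == length(p_adj))
  ifelse(p_adj <= alpha & log2fc > 0, "enriched",
  ifelse(p_adj <= alpha & log2fc < 0, "de_enriched", "not_significant"))
}

#' RPKM and per-gene z-scores
#'
#' Reads per kilobase of transcript per million mapped reads,
#' `count / (length_kb * total/1e6)`, followed by row-wise z-scoring
#' (constant rows map to 0). Genes without a length are dropped with a
#' warning.
#'
#' @param m a [count_matrix()] with `gene_length_kb` set.
#' @return gene x sample matrix of z-scores with the RPKM matrix attached
#'   as attribute `"rpkm"`.
#' @export
compute_rpkm_zscore <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$gene_length_kb)) stop("gene lengths are required for RPKM")
  len <- m$gene_length_kb[rownames(m$counts)]
  drop <- is.na(len)
  if (any(drop)) {
    warning(sum(drop), " gene(s) without a length dropped from RPKM")
  }
  counts <- m$counts[!drop, , drop = FALSE]
  len <- len[!drop]
  totals <- colSums(m$counts)
  if (any(totals <= 0)) stop("every sample must have positive total counts")
  rpkm <- sweep(counts / len, 2, totals / 1e6, "/")
  z <- t(apply(rpkm, 1, function(r) {
    s <- stats::sd(r)
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(rpkm)
  attr(z, "rpkm") <- rpkm
  z
}

#' Validate a known marker panel against an enrichment fit
#'
#' The sanity gate applied before trusting an IP contrast: every known
#' GABA-neuron marker must be called enriched and no dopamine-neuron
#' marker may be, at the fit's significance level.
#'
#' @param fit an [nb_enrichment()] object.
#' @param gaba_markers,da_markers character vectors of gene ids.
#' @return data.frame (class `"marker_panel"`) with columns `marker`,
#'   `role`, `status`, `ok`; attribute `"pass"` gives the overall verdict
#'   (missing markers fail).
#' @export
validate_marker_panel <- function(fit, gaba_markers, da_markers) {
  stopifnot(inherits(fit, "nb_enrichment"))
  res <- fit$results
  status_of <- function(g) {
    i <- match(g, res$gene_id)
    if (is.na(i)) "missing" else res$call[i]
  }
  markers <- c(gaba_markers, da_markers)
  role <- c(rep("gaba", length(gaba_markers)), rep("da", length(da_markers)))
  status <- vapply(markers, status_of, character(1))
  ok <- ifelse(role == "gaba", status == "enriched",
               status != "enriched" & status != "missing")
  out <- data.frame(marker = markers, role = role, status = status, ok = ok,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pass") <- all(ok)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' @export
print.nb_enrichment <- function(x, ...) {
  cat("Negative-binomial differential enrichment\n")
  cat(sprintf("  contrast: %s vs %s (%d vs %d samples)\n", x$numerator,
              x$denominator, x$n_samples[1], x$n_samples[2]))
  tab <- table(factor(x$results$call,
                      levels = c("enriched", "de_enriched", "not_significant")))
  cat(sprintf("  %d genes tested at alpha = %g: %d enriched, %d de-enriched, %d not significant\n",
              nrow(x$results), x$alpha, tab[["enriched"]],
              tab[["de_enriched"]], tab[["not_significant"]]))
  cat(sprintf("  pooled dispersion %.4g, prior df %g\n", x$pooled_dispersion,
              x$prior_df))
  invisible(x)
}

#' @export
summary.nb_enrichment <- function(object, ...) {
  res <- object$results[order(object$results$p_adj), ]
  out <- list(results = res,
              n = table(object$results$call),
              alpha = object$alpha,
              contrast = c(object$numerator, object$denominator))
  class(out) <- "summary.nb_enrichment"
  out
}

#' @export
print.summary.nb_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment summary (%s vs %s), alpha = %g\n", x$contrast[1],
              x$contrast[2], x$alpha))
  print(utils::head(x$results, 10), digits = 3)
  invisible(x)
}

#' @export
coef.nb_enrichment <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$gene_id)
}

#' Volcano plot of an enrichment fit
#'
#' @param x an [nb_enrichment()] object.
#' @param y ignored.
#' @param ... passed to [plot()].
#' @export
plot.nb_enrichment <- function(x, y, ...) {
  res <- x$results
  col <- c(enriched = "firebrick", de_enriched = "forestgreen",
           not_significant = "grey60")[res$call]
  graphics::plot(res$log2fc, -log10(pmax(res$p_adj, 1e-300)), col = col,
                 pch = 16, cex = 0.6, xlab = "log2 fold change",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Write / read differential-enrichment results as TSV
#'
#' @param fit an [nb_enrichment()] object (or its `results` data.frame).
#' @param path output file.
#' @return `read_de_results` returns the results data.frame.
#' @export
write_de_results <- function(fit, path) {
  res <- if (inherits(fit, "nb_enrichment")) fit$results else fit
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
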