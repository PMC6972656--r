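# Population-fraction estimation against the reference gene and the
# contracting filter funnel that turns the enriched set into the candidate
# shortlist.

#' Population fractions relative to the reference gene
#'
#' Divides each gene's regional expression density by the reference
#' gene's, interpreting the ratio as the fraction of the reference-defined
#' population (all GABA neurons, for a Vgat-like reference) expressing the
#' gene. Fractions above 1 indicate expression beyond that population
#' (multiple cell types) and are flagged.
#'
#' @param summaries data.frame from [summarize_ish()] /
#'   [read_summary_table()] containing the reference gene.
#' @param reference_gene id of the reference gene; its density must be
#'   positive.
#' @param lo,hi the mosaicism window (defaults 0.05 and 0.50) used to set
#'   the `in_window` flag.
#' @return data.frame (reference row excluded): `gene_id`, `fraction`,
#'   `above_reference`, `in_window`, plus the input density/intensity.
#' @export
population_fractions <- function(summaries, reference_gene, lo = 0.05,
                                 hi = 0.50) {
  .check_window(lo, hi)
  i <- match(reference_gene, summaries$gene_id)
  if (is.na(i)) stop("reference gene '", reference_gene,
                     "' absent from the summaries")
  ref_density <- summaries$expression_density[i]
  if (!is.finite(ref_density) || ref_density <= 0)
    stop("reference gene density must be positive (got ", ref_density, ")")
  out <- summaries[-i, , drop = FALSE]
  out$fraction <- out$expression_density / ref_density
  out$above_reference <- out$fraction > 1
  out$in_window <- out$fraction >= lo & out$fraction <= hi
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  attr(out, "reference_density") <- ref_density
  out
}

#' Population fraction of one gene
#'
#' Scalar form of [population_fractions()] for two single-gene summaries.
#'
#' @param gene,reference one-row summaries as from [summarize_gene()].
#' @inheritParams population_fractions
#' @return one-row data.frame with `fraction`, `above_reference`,
#'   `in_window`.
#' @export
compute_fraction <- function(gene, reference, lo = 0.05, hi = 0.50) {
  population_fractions(rbind(gene, reference),
                       reference_gene = reference$gene_id, lo = lo, hi = hi)
}

.check_window <- function(lo, hi) {
  if (!(lo > 0 && lo < hi && hi <= 1))
    stop("mosaicism window must satisfy 0 < lo < hi <= 1")
}

#' Apply the mosaicism window
#'
#' Keeps genes whose population fraction lies in `[lo, hi]`, both bounds
#' inclusive. The defaults select genes expressed in between 5% and 50%
#' of the reference population.
#'
#' @param fractions data.frame from [population_fractions()].
#' @param lo,hi window bounds.
#' @return character vector of retained gene ids.
#' @export
apply_window <- function(fractions, lo = 0.05, hi = 0.50) {
  .check_window(lo, hi)
  fractions$gene_id[fractions$fraction >= lo & fractions$fraction <= hi]
}

#' Retain mosaically expressed genes
#'
#' Drops genes flagged as absent from the region or widespread across it,
#' keeping the mosaic ones. The flags default to curated input (the
#' manual image-inspection route); genes with an `unknown` flag are
#' retained with a warning rather than silently dropped.
#'
#' @param genes character vector of gene ids.
#' @param annotations annotation data.frame with a `pattern_flag` column.
#' @return subset of `genes`.
#' @export
filter_by_pattern <- function(genes, annotations) {
  flag <- annotations$pattern_flag[match(genes, annotations$gene_id)]
  flag[is.na(flag)] <- "unknown"
  if (any(flag == "unknown"))
    warning(sum(flag == "unknown"),
            " gene(s) with unknown pattern retained for manual inspection")
  genes[flag %in% c("mosaic", "unknown")]
}

#' Automated pattern proxy from a grid (non-canonical)
#'
#' A clearly labeled automated stand-in for manual image inspection:
#' classifies a gene `absent` when its regional density falls below a
#' floor, `widespread` when it exceeds the reference density, `mosaic`
#' otherwise. The score is density / reference density.
#'
#' @inheritParams compute_density
#' @param reference_density positive density of the reference gene.
#' @param floor absence floor on density (default 0.005).
#' @return list with `class` and `score`.
#' @export
score_pattern_proxy <- function(grid, mask, threshold, reference_density,
                                floor = 0.005) {
  if (reference_density <= 0) stop("reference_density must be positive")
  d <- compute_density(grid, mask, threshold)
  cls <- if (d < floor) "absent"
         else if (d > reference_density) "widespread"
         else "mosaic"
  list(class = cls, score = d / reference_density)
}

#' Retain genes with an available cre-driver line
#'
#' @inheritParams filter_by_pattern
#' @return subset of `genes` with `cre_available` true (genes missing
#'   from the table are dropped).
#' @export
filter_by_cre <- function(genes, annotations) {
  cre <- annotations$cre_available[match(genes, annotations$gene_id)]
  genes[!is.na(cre) & cre]
}

#' The default literature exclusion list
#'
#' Genes removed from the shortlist on prior evidence: a pan-population
#' marker, two genes with reported dopamine-neuron expression, a glial
#' marker, and one whose antibodies fail in the region.
#'
#' @return named character vector, gene id -> reason.
#' @export
default_exclusions <- function() {
  c(Gata3 = "expressed in all midbrain GABA neurons",
    Nts   = "evidence of expression in midbrain dopamine neurons",
    En2   = "evidence of expression in midbrain dopamine neurons",
    S100b = "glial marker; possible glial contamination or false positive",
    Sst   = "immunolabelling fails to reveal positive cells in the region")
}

#' Apply literature exclusions
#'
#' Set difference against the configured exclusion list; every applied
#' exclusion is reported with its reason, and exclusions absent from the
#' gene set are a logged no-op.
#'
#' @param genes character vector of gene ids.
#' @param exclusions named character vector (id -> reason) or bare
#'   character vector; default [default_exclusions()].
#' @return subset of `genes`.
#' @export
apply_exclusions <- function(genes, exclusions = default_exclusions()) {
  if (length(exclusions) == 0L) return(genes)
  ids <- if (is.null(names(exclusions))) exclusions else names(exclusions)
  reasons <- if (is.null(names(exclusions)))
    rep("excluded by configuration", length(exclusions)) else unname(exclusions)
  hit <- ids %in% genes
  for (k in which(hit))
    message("excluding ", ids[k], ": ", reasons[k])
  if (any(!hit))
    message("exclusion(s) not present upstream (no-op): ",
            paste(ids[!hit], collapse = ", "))
  genes[!genes %in% ids]
}

#' Build a funnel ledger from ordered stage outputs
#'
#' Records the gene set surviving each pipeline stage, enforcing that
#' every stage is a subset of the previous one. A violation is an
#' integrity error naming the offending genes, never silently repaired.
#'
#' @param stages named list of character vectors, in pipeline order.
#' @return object of class `"funnel_ledger"`: data.frame of
#'   `stage`/`count` with the gene sets in attribute `"sets"`.
#' @export
build_funnel <- function(stages) {
  if (length(stages) == 0L) stop("at least one stage is required")
  if (is.null(names(stages)) || any(!nzchar(names(stages))))
    stop("stages must be named")
  sets <- lapply(stages, unique)
  for (k in seq_along(sets)[-1]) {
    extra <- setdiff(sets[[k]], sets[[k - 1]])
    if (length(extra))
      stop("funnel stage '", names(sets)[k], "' contains gene(s) absent ",
           "from stage '", names(sets)[k - 1], "': ",
           paste(extra, collapse = ", "))
  }
  out <- data.frame(stage = names(sets),
                    count = vapply(sets, length, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sets") <- sets
  class(out) <- c("funnel_ledger", "data.frame")
  out
}

#' @export
print.funnel_ledger <- function(x, ...) {
  cat("Prioritisation funnel\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-28s %6d\n", x$stage[i], x$count[i]))
  invisible(x)
}

#' Write a funnel ledger as TSV
#'
#' @param funnel a [build_funnel()] ledger.
#' @param path output file; columns `stage`, `count`, `genes`
#'   (';'-joined).
#' @export
write_funnel <- function(funnel, path) {
  sets <- attr(funnel, "sets")
  out <- data.frame(stage = funnel$stage, count = funnel$count,
                    genes = vapply(sets, paste, character(1), collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
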