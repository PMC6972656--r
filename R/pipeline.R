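# End-to-end orchestration: enrichment -> ontology restriction -> regional
# density -> mosaicism window -> pattern / cre / exclusion filters ->
# funnel ledger and candidate report, with an optional co-localisation
# stage when cell tables are supplied.

#' Pipeline configuration
#'
#' Collects every tunable of the screen: the significance level of the
#' enrichment call, the mosaicism window on the population fraction, the
#' reference gene anchoring that fraction, the voxel detection threshold,
#' the ontology categories, the literature exclusions with their reasons,
#' and whether the expression-pattern step uses curated flags (the
#' default, mirroring manual image inspection) or the automated,
#' non-canonical density proxy.
#'
#' @param alpha adjusted-p significance level, in (0, 1). Default 0.05.
#' @param window_lo,window_hi inclusive mosaicism window on the
#'   population fraction. Defaults 0.05 and 0.50.
#' @param reference_gene id of the pan-population reference gene.
#'   Default `"Vgat"`.
#' @param threshold voxel detection threshold. Default 1.
#' @param categories ontology labels (default [default_categories()]).
#' @param exclusions named id -> reason vector
#'   (default [default_exclusions()]).
#' @param pattern_mode `"curated"` or `"proxy"`.
#' @param seed integer recorded in provenance.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(alpha = 0.05, window_lo = 0.05,
                            window_hi = 0.50, reference_gene = "Vgat",
                            threshold = 1,
                            categories = default_categories(),
                            exclusions = default_exclusions(),
                            pattern_mode = c("curated", "proxy"),
                            seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  .check_window(window_lo, window_hi)
  pattern_mode <- match.arg(pattern_mode)
  structure(list(alpha = alpha, window_lo = window_lo,
                 window_hi = window_hi,
                 reference_gene = as.character(reference_gene),
                 threshold = threshold, categories = categories,
                 exclusions = exclusions, pattern_mode = pattern_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()];
#' `exclusions` is a mapping of gene id to reason. Missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      names(formals(pipeline_config)))]
  if (!is.null(args$exclusions)) args$exclusions <- unlist(args$exclusions)
  if (!is.null(args$categories)) args$categories <- unlist(args$categories)
  do.call(pipeline_config, args)
}

#' Run the full marker-prioritisation screen
#'
#' Executes the pipeline on in-memory inputs: fits the NB enrichment test,
#' restricts the enriched set to the ontology categories, quantifies
#' regional expression density, converts it to population fractions
#' against the reference gene, applies the mosaicism window, the pattern,
#' cre-driver and literature-exclusion filters, and assembles the funnel
#' ledger and candidate report. Any stage failure aborts with the stage
#' name; partially written outputs are removed.
#'
#' @param counts a [count_matrix()].
#' @param annotations annotation data.frame (categories, cre flags,
#'   pattern flags).
#' @param ish either a list with `grids` and `mask` (the grid pathway) or
#'   a per-gene summary data.frame as from [read_summary_table()].
#' @param config a [pipeline_config()].
#' @param cells optional cell table (or named list of cell tables, one
#'   per candidate) for the co-localisation stage.
#' @param out_dir optional directory; when given, every stage output is
#'   persisted as TSV.
#' @return object of class `"marker_screen"`: list with `fit`
#'   (the [nb_enrichment()] object), `summaries`, `fractions`, `funnel`,
#'   `candidates` (the report data.frame), `colocalization` (or `NULL`)
#'   and `provenance`.
#' @export
run_pipeline <- function(counts, annotations, ish, config = pipeline_config(),
                         cells = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  on_fail <- function(stage, e) {
    if (length(written)) unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  persist <- function(writer, ..., file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(out_dir, file)
      writer(..., p)
      written <<- c(written, p)
    }
  }

  fit <- tryCatch(nb_enrichment(counts, alpha = config$alpha),
                  error = function(e) on_fail("differential_enrichment", e))
  persist(write_de_results, fit, file = "de_results.tsv")
  tested <- fit$results$gene_id
  enriched <- fit$results$gene_id[fit$results$call == "enriched"]

  in_categories <- tryCatch(
    filter_by_categories(enriched, annotations, config$categories),
    error = function(e) on_fail("ontology_filter", e))

  summaries <- tryCatch({
    if (is.data.frame(ish)) ish
    else summarize_ish(ish$grids, ish$mask, config$threshold)
  }, error = function(e) on_fail("ish_density", e))

  fractions <- tryCatch(
    population_fractions(summaries, config$reference_gene,
                         lo = config$window_lo, hi = config$window_hi),
    error = function(e) on_fail("population_fraction", e))

  in_window <- tryCatch(
    intersect(in_categories,
              apply_window(fractions, config$window_lo, config$window_hi)),
    error = function(e) on_fail("mosaicism_window", e))

  pattern_ok <- tryCatch({
    if (config$pattern_mode == "curated") {
      filter_by_pattern(in_window, annotations)
    } else {
      if (is.data.frame(ish))
        stop("pattern_mode 'proxy' needs expression grids, not summaries")
      ref_density <- attr(fractions, "reference_density")
      keep <- vapply(in_window, function(g) {
        cls <- vapply(ish$grids[[g]], function(gr)
          score_pattern_proxy(gr, ish$mask, config$threshold,
                              ref_density)$class, character(1))
        # a gene is mosaic when its replicate grids agree by majority
        names(sort(table(cls), decreasing = TRUE))[1] == "mosaic"
      }, logical(1))
      in_window[keep]
    }
  }, error = function(e) on_fail("pattern_filter", e))

  with_cre <- tryCatch(filter_by_cre(pattern_ok, annotations),
                       error = function(e) on_fail("cre_filter", e))
  candidates <- tryCatch(apply_exclusions(with_cre, config$exclusions),
                         error = function(e) on_fail("exclusions", e))

  funnel <- tryCatch(
    build_funnel(list(tested = tested, enriched = enriched,
                      in_categories = in_categories,
                      in_window = in_window, mosaic_pattern = pattern_ok,
                      cre_available = with_cre, candidates = candidates)),
    error = function(e) on_fail("funnel", e))
  persist(write_funnel, funnel, file = "funnel.tsv")

  res <- fit$results
  report <- data.frame(symbol = candidates,
                       log2fc = res$log2fc[match(candidates, res$gene_id)],
                       p_adj = res$p_adj[match(candidates, res$gene_id)],
                       fraction = fractions$fraction[match(candidates,
                                                           fractions$gene_id)],
                       expression_density =
                         summaries$expression_density[match(candidates,
                                                            summaries$gene_id)],
                       cre_available = TRUE,
                       stringsAsFactors = FALSE, row.names = NULL)
  persist(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE),
          report, file = "candidates.tsv")

  coloc <- NULL
  if (!is.null(cells)) {
    coloc <- tryCatch({
      if (is.data.frame(cells)) {
        summarize_colocalization(cells)
      } else {
        lapply(cells, summarize_colocalization)
      }
    }, error = function(e) on_fail("colocalization", e))
  }

  screen <- structure(
    list(fit = fit, summaries = summaries, fractions = fractions,
         funnel = funnel, candidates = report, colocalization = coloc,
         provenance = list(config = unclass(config), seed = config$seed,
                           pattern_mode = config$pattern_mode,
                           non_canonical_pattern =
                             config$pattern_mode == "proxy",
                           package_version =
                             as.character(utils::packageVersion("mosaicscreen")),
                           timestamp_free = TRUE)),
    class = "marker_screen")
  if (!is.null(out_dir)) write_report(screen, out_dir)
  screen
}

#' @export
print.marker_screen <- function(x, ...) {
  cat("Mosaic-marker screen\n")
  print(x$funnel)
  if (nrow(x$candidates)) {
    cat("Candidates:\n")
    print(x$candidates, digits = 3, row.names = FALSE)
  } else cat("Candidates: none retained\n")
  if (isTRUE(x$provenance$non_canonical_pattern))
    cat("NOTE: pattern step used the automated proxy (non-canonical)\n")
  invisible(x)
}

#' @export
summary.marker_screen <- function(object, ...) {
  list(funnel = object$funnel, candidates = object$candidates,
       alpha = object$provenance$config$alpha,
       n_tested = object$funnel$count[1])
}

#' Write the candidate report of a screen
#'
#' Persists the candidate table, the funnel ledger, a provenance YAML
#' (config and seed) and a human-readable text rendering.
#'
#' @param screen a [run_pipeline()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(screen, dir) {
  stopifnot(inherits(screen, "marker_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(screen$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_funnel(screen$funnel, file.path(dir, "funnel.tsv"))
  prov <- screen$provenance
  prov$config$exclusions <- as.list(prov$config$exclusions)
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(screen)
  if (!is.null(screen$colocalization)) {
    if (inherits(screen$colocalization, "coloc_summary")) {
      print(screen$colocalization)
    } else {
      for (g in names(screen$colocalization)) {
        cat("\n", g, ":\n", sep = "")
        print(screen$colocalization[[g]])
      }
    }
  }
  invisible(dir)
}
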