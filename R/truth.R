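#' Planted-truth table for synthetic experiments
#'
#' Builds and validates the ground-truth table that drives every synthetic
#' input: the negative-binomial count generator, the voxel expression grids,
#' and the annotation tables. Each row is one gene with its planted
#' enrichment (log2 fold change of the GABA-IP over the dopamine-IP
#' population), its baseline expression, NB dispersion, the fraction of the
#' GABA population expressing it, a spatial pattern class, ontology
#' categories, and cre-driver availability.
#'
#' `expressing_fraction` is on the scale where 1 means "expressed by the
#' whole GABA population" (the reference-gene level); values above 1 encode
#' expression spilling into additional cell types, and are capped at 1.5.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param planted_log2fc numeric, planted log2 fold change (GABA-IP vs
#'   DA-IP). Default 0.
#' @param mean_expression numeric > 0, expected normalized count in the
#'   DA-IP group. Default 100.
#' @param dispersion numeric >= 0, NB dispersion `a` in the
#'   `variance = mu + a * mu^2` parameterization. Default 0.1.
#' @param expressing_fraction numeric in `[0, 1.5]`, fraction of the GABA
#'   population (i.e. of the reference gene's voxel probability) expressing
#'   the gene. Default 0.3.
#' @param pattern_class one of `"absent"`, `"mosaic"`, `"widespread"` per
#'   gene; if `NULL` (default) it is derived from `expressing_fraction`:
#'   below `absence_floor` is absent, above 1 is widespread, else mosaic.
#' @param categories list of character vectors (one per gene) of ontology
#'   category labels; default empty.
#' @param cre_available logical, whether a cre-driver line exists. Default
#'   `TRUE`.
#' @param marker_class one of `"gaba_marker"`, `"da_marker"`, `"none"`.
#'   Default `"none"`.
#' @param absence_floor expressing fraction below which a gene counts as
#'   absent from the region. Default 0.005.
#'
#' @return a `data.frame` of class `"truth_table"` with one row per gene and
#'   a `categories` list column.
#' @examples
#' tt <- truth_table(c("g1", "g2"), planted_log2fc = c(2, 0),
#'                   expressing_fraction = c(0.3, 1))
#' tt$pattern_class
#' @export
truth_table <- function(gene_id,
                        planted_log2fc = 0,
                        mean_expression = 100,
                        dispersion = 0.1,
                        expressing_fraction = 0.3,
                        pattern_class = NULL,
                        categories = NULL,
                        cre_available = TRUE,
                        marker_class = "none",
                        absence_floor = 0.005) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (n == 0L) stop("truth_table needs at least one gene")
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")

  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(sprintf("'%s' must have length 1 or %d", what, n))
    x
  }
  planted_log2fc <- rec(as.numeric(planted_log2fc), "planted_log2fc")
  mean_expression <- rec(as.numeric(mean_expression), "mean_expression")
  dispersion <- rec(as.numeric(dispersion), "dispersion")
  expressing_fraction <- rec(as.numeric(expressing_fraction), "expressing_fraction")
  cre_available <- rec(as.logical(cre_available), "cre_available")
  marker_class <- rec(as.character(marker_class), "marker_class")

  if (any(!is.finite(mean_expression)) || any(mean_expression <= 0))
    stop("mean_expression must be finite and > 0")
  if (any(!is.finite(dispersion)) || any(dispersion < 0))
    stop("dispersion must be finite and >= 0")
  if (any(expressing_fraction < 0) || any(expressing_fraction > 1.5))
    stop("expressing_fraction must lie in [0, 1.5]")
  if (!all(marker_class %in% c("gaba_marker", "da_marker", "none")))
    stop("marker_class must be one of 'gaba_marker', 'da_marker', 'none'")

  if (is.null(pattern_class)) {
    pattern_class <- ifelse(expressing_fraction < absence_floor, "absent",
                     ifelse(expressing_fraction > 1, "widespread", "mosaic"))
  } else {
    pattern_class <- rec(as.character(pattern_class), "pattern_class")
    if (!all(pattern_class %in% c("absent", "mosaic", "widespread")))
      stop("pattern_class must be 'absent', 'mosaic' or 'widespread'")
    # absence must agree with the expressing fraction either way round
    bad <- xor(pattern_class == "absent", expressing_fraction < absence_floor)
    if (any(bad))
      stop("pattern_class 'absent' must coincide with expressing_fraction below ",
           absence_floor, " (offending: ", paste(gene_id[bad], collapse = ", "), ")")
  }

  if (is.null(categories)) categories <- rep(list(character(0)), n)
  if (!is.list(categories)) categories <- list(categories)
  if (length(categories) == 1L) categories <- rep(categories, n)
  if (length(categories) != n) stop("'categories' must have length 1 or ", n)
  categories <- lapply(categories, as.character)

  out <- data.frame(gene_id = gene_id,
                    planted_log2fc = planted_log2fc,
                    mean_expression = mean_expression,
                    dispersion = dispersion,
                    expressing_fraction = expressing_fraction,
                    pattern_class = pattern_class,
                    cre_available = cre_available,
                    marker_class = marker_class,
                    stringsAsFactors = FALSE)
  out$categories <- categories
  attr(out, "absence_floor") <- absence_floor
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. The defaults are the
#' study conditions emulated throughout the package: three biological
#' replicates per immunoprecipitated group, moderate library-size variation,
#' a region mask of roughly 10^4 voxels, and a reference gene (the Vgat
#' analogue, expressed by the whole GABA population) whose per-voxel
#' expressing probability anchors the population-fraction scale.
#'
#' @param n_genes number of genes simulated when a truth table is built
#'   implicitly; informational otherwise.
#' @param n_replicates_per_group integer >= 2 biological replicates per
#'   group (default 3).
#' @param library_size_range length-2 numeric, range of the uniform
#'   distribution the per-sample size factors are drawn from.
#' @param grid_shape integer triple, voxel grid dimensions `(x, y, z)`.
#'   The region mask is the inner box two voxels in from every face
#'   (10,816 voxels at the default 30 x 30 x 20).
#' @param reference_gene id of the reference gene; must be present in any
#'   truth table used with the grid simulator.
#' @param reference_expressing_probability per-voxel probability that the
#'   reference gene expresses inside the region, in (0, 1].
#' @param detection_threshold voxel intensity strictly above which a voxel
#'   counts as expressing.
#' @param background_intensity upper bound of the background signal
#'   (uniform on `[0, background_intensity]`).
#' @param expressing_intensity location of the expressing-voxel signal
#'   (log-normal jitter with sdlog 0.1 around it); must exceed the
#'   detection threshold.
#' @param seed integer master seed; per-stage substreams are derived from
#'   it by fixed offsets (counts +1, grids +2, cell tables +3,
#'   annotations +4).
#' @return a list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$grid_shape
#' @export
sim_config <- function(n_genes = 100,
                       n_replicates_per_group = 3,
                       library_size_range = c(0.7, 1.3),
                       grid_shape = c(30, 30, 20),
                       reference_gene = "Vgat",
                       reference_expressing_probability = 0.2,
                       detection_threshold = 1,
                       background_intensity = 0.2,
                       expressing_intensity = 10,
                       seed = 1L) {
  n_replicates_per_group <- as.integer(n_replicates_per_group)
  if (is.na(n_replicates_per_group) || n_replicates_per_group < 2L)
    stop("n_replicates_per_group must be an integer >= 2")
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stop("library_size_range must be an increasing positive pair")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 5L))
    stop("grid_shape must be three integers >= 5")
  if (!(reference_expressing_probability > 0 && reference_expressing_probability <= 1))
    stop("reference_expressing_probability must lie in (0, 1]")
  if (!(expressing_intensity > detection_threshold &&
        detection_threshold >= background_intensity &&
        background_intensity >= 0))
    stop("need expressing_intensity > detection_threshold >= background_intensity >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates_per_group = n_replicates_per_group,
                 library_size_range = as.numeric(library_size_range),
                 grid_shape = grid_shape,
                 reference_gene = as.character(reference_gene),
                 reference_expressing_probability = reference_expressing_probability,
                 detection_threshold = detection_threshold,
                 background_intensity = background_intensity,
                 expressing_intensity = expressing_intensity,
                 seed = as.integer(seed)),
            class = "sim_config")
}
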