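# Synthetic-data generators. All randomness flows from config$seed through
# fixed per-stage offsets so the full input set is reproducible from one
# integer.

.seed_offsets <- c(counts = 1L, grids = 2L, cells = 3L, annotations = 4L)

.with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + .seed_offsets[[stage]])
  expr
}

#' Simulate a gene x sample count matrix from planted truth
#'
#' Draws negative-binomial counts for two immunoprecipitated groups
#' (GABA-IP and DA-IP). The DA-IP group mean of gene g is
#' `s_j * mean_expression_g`; the GABA-IP mean is additionally scaled by
#' `2^planted_log2fc_g`. Variance follows `mu + dispersion * mu^2`
#' (dispersion 0 degenerates to Poisson). Per-sample size factors `s_j`
#' are drawn uniformly from `config$library_size_range`.
#'
#' @param truth a [truth_table()].
#' @param config a [sim_config()].
#' @return a [count_matrix()] whose sample sheet labels the first
#'   `n_replicates_per_group` samples `GABA_IP` and the rest `DA_IP`, with
#'   the true size factors and gene lengths attached.
#' @examples
#' tt <- truth_table(paste0("g", 1:5), planted_log2fc = c(2, 0, 0, 0, -1))
#' cm <- simulate_counts(tt, sim_config(seed = 1))
#' dim(cm$counts)
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  if (any(truth$mean_expression <= 0))
    stop("mean_expression must be positive for all genes")
  n <- config$n_replicates_per_group
  .with_stage_seed(config$seed, "counts", {
    sf <- stats::runif(2L * n, config$library_size_range[1],
                       config$library_size_range[2])
    mu_gaba <- truth$mean_expression * 2^truth$planted_log2fc
    mu_da <- truth$mean_expression
    g <- nrow(truth)
    counts <- matrix(0L, g, 2L * n)
    for (j in seq_len(2L * n)) {
      mu <- if (j <= n) mu_gaba else mu_da
      mu <- mu * sf[j]
      a <- truth$dispersion
      pois <- a <= 0
      col <- numeric(g)
      if (any(pois)) col[pois] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois)) col[!pois] <- stats::rnbinom(sum(!pois),
                                                   mu = mu[!pois],
                                                   size = 1 / a[!pois])
      counts[, j] <- col
    }
    lengths_kb <- stats::runif(g, 0.5, 10)
    sample_id <- c(paste0("GABA_IP_", seq_len(n)), paste0("DA_IP_", seq_len(n)))
    group <- rep(c("GABA_IP", "DA_IP"), each = n)
    dimnames(counts) <- list(truth$gene_id, sample_id)
    cm <- count_matrix(counts, group,
                       gene_length_kb = stats::setNames(lengths_kb, truth$gene_id))
    cm$true_size_factors <- stats::setNames(sf, sample_id)
    cm
  })
}

#' Simulate regional expression grids and the region mask
#'
#' Emulates quantified in situ hybridisation volumes: inside the region
#' mask each voxel of gene g expresses independently with probability
#' `expressing_fraction_g * reference_expressing_probability` (the
#' reference gene itself uses `reference_expressing_probability`);
#' expressing voxels get a log-normal signal around
#' `expressing_intensity`, all other voxels uniform background below the
#' detection threshold. Probabilities that scale above 1 are clipped with
#' a warning recorded in the grid's provenance attribute.
#'
#' @param truth a [truth_table()]; must contain `config$reference_gene`
#'   unless `add_reference = TRUE` (the default), in which case a
#'   reference row with expressing fraction 1 is implied.
#' @param config a [sim_config()].
#' @param n_experiments replicate grids per gene (default 1).
#' @param clustered if `TRUE`, expressing voxels are grown around seeded
#'   blob centres instead of salt-and-pepper, keeping the expected
#'   expressing fraction; exercises pattern-inspection proxies.
#' @param add_reference add a reference-gene grid when the reference is
#'   absent from `truth`.
#' @return a list with `grids` (named list: per gene, a list of
#'   `expression_grid` arrays) and `mask` (a [region_mask()], the inner
#'   box of the grid, region id 1).
#' @examples
#' tt <- truth_table("g1", expressing_fraction = 0.3)
#' sim <- simulate_expression_grids(tt, sim_config(seed = 2))
#' names(sim$grids)
#' @export
simulate_expression_grids <- function(truth, config, n_experiments = 1L,
                                      clustered = FALSE, add_reference = TRUE) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  shape <- config$grid_shape
  lab <- array(0L, dim = shape)
  lab[3:(shape[1] - 2), 3:(shape[2] - 2), 3:(shape[3] - 2)] <- 1L
  mask <- region_mask(lab, region_id = 1L)
  inside <- which(lab == 1L)
  n_in <- length(inside)

  genes <- truth$gene_id
  frac <- stats::setNames(truth$expressing_fraction, genes)
  if (!config$reference_gene %in% genes) {
    if (!add_reference)
      stop("reference gene '", config$reference_gene, "' absent from truth")
    frac[config$reference_gene] <- 1
    genes <- c(genes, config$reference_gene)
  } else {
    frac[config$reference_gene] <- 1
  }

  .with_stage_seed(config$seed, "grids", {
    grids <- lapply(genes, function(g) {
      p <- frac[[g]] * config$reference_expressing_probability
      clipped <- FALSE
      if (p > 1) {
        warning("expressing probability for ", g, " clipped from ",
                signif(p, 3), " to 1")
        p <- 1
        clipped <- TRUE
      }
      lapply(seq_len(n_experiments), function(e) {
        vals <- array(stats::runif(prod(shape), 0, config$background_intensity),
                      dim = shape)
        expr_idx <- if (clustered) {
          .clustered_voxels(inside, shape, p)
        } else {
          inside[stats::runif(n_in) < p]
        }
        if (length(expr_idx))
          vals[expr_idx] <- config$expressing_intensity *
            exp(stats::rnorm(length(expr_idx), 0, 0.1))
        expression_grid(vals, gene_id = g,
                        experiment_id = sprintf("%s_exp%d", g, e),
                        provenance = list(expressing_probability = p,
                                          clipped = clipped,
                                          clustered = clustered))
      })
    })
    names(grids) <- genes
    list(grids = grids, mask = mask)
  })
}

# grow blobs around seeded centres until the expected voxel count is hit;
# spatial texture only -- the marginal expressing fraction is preserved.
.clustered_voxels <- function(inside, shape, p) {
  target <- round(p * length(inside))
  if (target == 0L) return(integer(0))
  n_blobs <- max(1L, round(target / 60))
  coords <- arrayInd(inside, shape)
  centres <- coords[sample.int(nrow(coords), n_blobs, replace = TRUE), ,
                    drop = FALSE]
  # distance of every in-region voxel to its nearest centre; take the
  # closest `target` voxels
  d2 <- rep(Inf, nrow(coords))
  for (b in seq_len(n_blobs)) {
    db <- (coords[, 1] - centres[b, 1])^2 + (coords[, 2] - centres[b, 2])^2 +
      (coords[, 3] - centres[b, 3])^2
    d2 <- pmin(d2, db)
  }
  inside[order(d2 + stats::runif(length(d2)))[seq_len(target)]]
}

#' Simulate a per-cell immunolabelling table
#'
#' Emulates counted microscopy fields: each cell is assigned a
#' neurochemical class (HA+ only, TH+ only, HA+ and TH+, or neither) and
#' then candidate-marker positivity with a class-conditional probability.
#' HA and TH are mutually exclusive except for a small configurable
#' double-positive fraction of the HA (GABA) population.
#'
#' @param p_candidate_given_gaba probability a HA+ cell expresses the
#'   candidate.
#' @param p_candidate_given_da probability a TH+-only cell expresses the
#'   candidate.
#' @param cells_per_animal positive integer.
#' @param n_animals positive integer.
#' @param gaba_proportion proportion of (HA or TH) cells that are HA+.
#' @param double_positive_rate fraction of the HA+ population that is also
#'   TH+ (default 0.02).
#' @param other_proportion proportion of cells that are neither HA+ nor
#'   TH+ (default 0).
#' @param p_candidate_given_other candidate probability for those cells
#'   (default 0).
#' @param seed integer seed (offset internally, like the other
#'   generators).
#' @return a `data.frame` (class `"cell_table"`) with columns `cell_id`,
#'   `animal_id`, `candidate`, `ha`, `th` (logical).
#' @examples
#' ct <- simulate_cell_table(0.4, 0.05, cells_per_animal = 100,
#'                           n_animals = 3, gaba_proportion = 0.35, seed = 3)
#' table(ct$ha, ct$th)
#' @export
simulate_cell_table <- function(p_candidate_given_gaba,
                                p_candidate_given_da,
                                cells_per_animal,
                                n_animals,
                                gaba_proportion,
                                double_positive_rate = 0.02,
                                other_proportion = 0,
                                p_candidate_given_other = 0,
                                seed = 1L) {
  probs <- c(p_candidate_given_gaba, p_candidate_given_da, gaba_proportion,
             double_positive_rate, other_proportion, p_candidate_given_other)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  cells_per_animal <- as.integer(cells_per_animal)
  n_animals <- as.integer(n_animals)
  if (cells_per_animal < 1L || n_animals < 1L)
    stop("cells_per_animal and n_animals must be positive")

  g <- gaba_proportion * (1 - other_proportion)
  p_class <- c(ha_only = g * (1 - double_positive_rate),
               both = g * double_positive_rate,
               th_only = (1 - gaba_proportion) * (1 - other_proportion),
               neither = other_proportion)

  .with_stage_seed(as.integer(seed), "cells", {
    rows <- lapply(seq_len(n_animals), function(a) {
      cls <- sample(names(p_class), cells_per_animal, replace = TRUE,
                    prob = p_class)
      ha <- cls %in% c("ha_only", "both")
      th <- cls %in% c("th_only", "both")
      p_cand <- ifelse(ha, p_candidate_given_gaba,
                ifelse(th, p_candidate_given_da, p_candidate_given_other))
      data.frame(cell_id = sprintf("a%d_c%d", a, seq_len(cells_per_animal)),
                 animal_id = paste0("animal_", a),
                 candidate = stats::runif(cells_per_animal) < p_cand,
                 ha = ha, th = th, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("cell_table", "data.frame")
    out
  })
}

#' Simulate a gene annotation table
#'
#' Copies each gene's true ontology categories, cre-driver availability and
#' pattern class from the truth table and sprinkles in random distractor
#' categories from the remaining universe, emulating a gene-ontology export.
#'
#' @param truth a [truth_table()].
#' @param category_universe character vector of all category labels
#'   (default [default_categories()]).
#' @param distractor_rate per-(gene, label) probability of adding a label
#'   the gene does not truly carry (default 0.1).
#' @param seed integer seed.
#' @return an annotation `data.frame` with list column `categories` and
#'   columns `gene_id`, `cre_available`, `pattern_flag`.
#' @examples
#' tt <- truth_table("g1", categories = list("receptors"))
#' ann <- simulate_annotations(tt, distractor_rate = 0, seed = 1)
#' ann$categories[[1]]
#' @export
simulate_annotations <- function(truth, category_universe = default_categories(),
                                 distractor_rate = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (length(category_universe) == 0L)
    stop("category_universe must be non-empty")
  .with_stage_seed(as.integer(seed), "annotations", {
    cats <- lapply(seq_len(nrow(truth)), function(i) {
      own <- truth$categories[[i]]
      pool <- setdiff(category_universe, own)
      extra <- pool[stats::runif(length(pool)) < distractor_rate]
      sort(unique(c(own, extra)))
    })
    out <- data.frame(gene_id = truth$gene_id,
                      cre_available = truth$cre_available,
                      pattern_flag = truth$pattern_class,
                      stringsAsFactors = FALSE)
    out$categories <- cats
    out[, c("gene_id", "categories", "cre_available", "pattern_flag")]
  })
}

#' Generate every pipeline input from one truth table
#'
#' Convenience wrapper running all four simulators with the per-stage
#' substreams of `config$seed`, returning the complete in-memory input set
#' for [run_pipeline()].
#'
#' @inheritParams simulate_expression_grids
#' @param category_universe,distractor_rate passed to
#'   [simulate_annotations()].
#' @return list with `counts` ([count_matrix()]), `grids`, `mask`,
#'   `annotations`, and the `truth` and `config` used.
#' @export
simulate_inputs <- function(truth, config, n_experiments = 1L,
                            category_universe = default_categories(),
                            distractor_rate = 0.1, clustered = FALSE) {
  cm <- simulate_counts(truth, config)
  ish <- simulate_expression_grids(truth, config, n_experiments = n_experiments,
                                   clustered = clustered)
  ann <- simulate_annotations(truth, category_universe,
                              distractor_rate = distractor_rate,
                              seed = config$seed)
  list(counts = cm, grids = ish$grids, mask = ish$mask, annotations = ann,
       truth = truth, config = config)
}
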