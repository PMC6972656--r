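# Regional expression-density and expression-intensity quantification from
# voxel grids, the two quantities plotted against each other when screening
# atlas ISH data. Density = number of expressing voxels / number of region
# voxels; intensity = mean signal of the expressing voxels.

#' Construct an expression grid
#'
#' A 3-D array of non-negative per-voxel expression signal for one gene
#' and one experiment. Axis order is `(x, y, z)` with 0-based voxel
#' indices in any file metadata; no anatomical registration is implied.
#'
#' @param values numeric 3-D array, finite and >= 0.
#' @param gene_id,experiment_id identifiers.
#' @param provenance optional list carried along (e.g. clipping warnings
#'   from the simulator).
#' @return the array with class `"expression_grid"` and id attributes.
#' @export
expression_grid <- function(values, gene_id, experiment_id = gene_id,
                            provenance = NULL) {
  if (length(dim(values)) != 3L) stop("expression grid must be a 3-D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid values must be finite and >= 0")
  structure(values, class = "expression_grid", gene_id = gene_id,
            experiment_id = experiment_id, provenance = provenance)
}

#' Construct a region mask
#'
#' An integer label volume plus the label selecting the region of
#' interest.
#'
#' @param labels integer 3-D array of structure labels.
#' @param region_id label of the region to quantify.
#' @return list of class `"region_mask"`.
#' @export
region_mask <- function(labels, region_id) {
  if (length(dim(labels)) != 3L) stop("label volume must be a 3-D array")
  region_id <- as.integer(region_id)
  if (!any(labels == region_id)) stop("region ", region_id, " is empty")
  structure(list(labels = labels, region_id = region_id),
            class = "region_mask")
}

.region_values <- function(grid, mask) {
  if (!identical(dim(grid), dim(mask$labels)))
    stop("grid and mask shapes differ")
  sel <- mask$labels == mask$region_id
  if (!any(sel)) stop("region ", mask$region_id, " is empty")
  as.numeric(grid[sel])
}

#' Expression density of a grid within a region
#'
#' Fraction of in-region voxels whose signal exceeds the detection
#' threshold (strict inequality).
#'
#' @param grid an [expression_grid()] (any 3-D array works).
#' @param mask a [region_mask()] of the same shape.
#' @param threshold detection threshold, >= 0.
#' @return density in `[0, 1]`.
#' @export
compute_density <- function(grid, mask, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  v <- .region_values(grid, mask)
  mean(v > threshold)
}

#' Expression intensity of a grid within a region
#'
#' Sum of signal over expressing in-region voxels divided by the number
#' of expressing voxels, i.e. their mean signal. When no voxel expresses,
#' the intensity is undefined and `NA` is returned (never 0).
#'
#' @inheritParams compute_density
#' @return mean expressing-voxel signal, or `NA_real_` when none express.
#' @export
compute_intensity <- function(grid, mask, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  v <- .region_values(grid, mask)
  expr <- v[v > threshold]
  if (length(expr) == 0L) return(NA_real_)
  sum(expr) / length(expr)
}

#' Summarize one gene's grids into density and intensity
#'
#' Density and intensity are each averaged arithmetically over the gene's
#' replicate experiments; undefined (NA) intensities are dropped from the
#' intensity mean, and an all-undefined gene keeps `NA`.
#'
#' @param grids list of [expression_grid()]s for one gene (length >= 1).
#' @param mask a [region_mask()].
#' @param threshold detection threshold.
#' @return one-row data.frame: `gene_id`, `expression_density`,
#'   `expression_intensity`, `n_voxels`, `n_experiments`.
#' @export
summarize_gene <- function(grids, mask, threshold) {
  if (inherits(grids, "expression_grid")) grids <- list(grids)
  if (length(grids) == 0L) stop("at least one grid is required")
  dens <- vapply(grids, compute_density, numeric(1), mask = mask,
                 threshold = threshold)
  ints <- vapply(grids, compute_intensity, numeric(1), mask = mask,
                 threshold = threshold)
  gene <- attr(grids[[1]], "gene_id")
  if (is.null(gene)) gene <- NA_character_
  data.frame(gene_id = gene,
             expression_density = mean(dens),
             expression_intensity = if (all(is.na(ints))) NA_real_
                                    else mean(ints, na.rm = TRUE),
             n_voxels = sum(mask$labels == mask$region_id),
             n_experiments = length(grids),
             stringsAsFactors = FALSE)
}

#' Summarize every gene's grids
#'
#' @param grids_by_gene named list (gene id -> list of grids), e.g. the
#'   `grids` element of [simulate_expression_grids()].
#' @inheritParams summarize_gene
#' @return data.frame with one row per gene, as [summarize_gene()].
#' @export
summarize_ish <- function(grids_by_gene, mask, threshold) {
  rows <- lapply(names(grids_by_gene), function(g) {
    s <- summarize_gene(grids_by_gene[[g]], mask, threshold)
    s$gene_id <- g
    s
  })
  do.call(rbind, rows)
}

#' Read a per-experiment ISH summary table
#'
#' Ingests pre-quantified per-structure values: a TSV with header
#' `gene_id, experiment_id, expression_density, expression_intensity`.
#' Rows are grouped by gene and averaged exactly as [summarize_gene()]
#' does. Densities outside `[0, 1]` abort with a listing of the offending
#' rows.
#'
#' @param path file path.
#' @return data.frame with one row per gene (`n_voxels` is `NA`: unknown
#'   for pre-summarized input).
#' @export
read_summary_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "experiment_id", "expression_density",
            "expression_intensity")
  if (!all(need %in% names(raw)))
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(raw$expression_density) |
                 raw$expression_density < 0 | raw$expression_density > 1)
  if (length(bad))
    stop("expression_density outside [0, 1] in row(s): ",
         paste(bad, collapse = ", "))
  rows <- lapply(split(raw, raw$gene_id), function(d) {
    ints <- d$expression_intensity
    data.frame(gene_id = d$gene_id[1],
               expression_density = mean(d$expression_density),
               expression_intensity = if (all(is.na(ints))) NA_real_
                                      else mean(ints, na.rm = TRUE),
               n_voxels = NA_integer_,
               n_experiments = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Write per-experiment ISH values as a summary table
#'
#' Writes one row per (gene, experiment) so that [read_summary_table()]
#' round-trips to the same per-gene summaries as the grid pathway.
#'
#' @inheritParams summarize_ish
#' @param path output TSV.
#' @export
write_summary_table <- function(grids_by_gene, mask, threshold, path) {
  rows <- lapply(names(grids_by_gene), function(g) {
    grids <- grids_by_gene[[g]]
    if (inherits(grids, "expression_grid")) grids <- list(grids)
    do.call(rbind, lapply(grids, function(gr) {
      data.frame(gene_id = g,
                 experiment_id = attr(gr, "experiment_id"),
                 expression_density = compute_density(gr, mask, threshold),
                 expression_intensity = compute_intensity(gr, mask, threshold),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read expression grids as NIfTI volumes
#'
#' One volume per (gene, experiment) named `<gene>__<experiment>.nii.gz`,
#' plus `mask.nii.gz` for the label volume. `read_expression_grids`
#' reconstructs the named grid list and the mask.
#'
#' @param grids_by_gene named list of grid lists.
#' @param mask a [region_mask()].
#' @param dir output directory (created if needed).
#' @return `write_expression_grids` the directory;
#'   `read_expression_grids` a list with `grids` and `mask`.
#' @export
write_expression_grids <- function(grids_by_gene, mask, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(grids_by_gene)) {
    grids <- grids_by_gene[[g]]
    if (inherits(grids, "expression_grid")) grids <- list(grids)
    for (gr in grids) {
      f <- file.path(dir, paste0(g, "__", attr(gr, "experiment_id"),
                                 ".nii.gz"))
      RNifti::writeNifti(unclass(gr), f)
    }
  }
  RNifti::writeNifti(mask$labels, file.path(dir, "mask.nii.gz"))
  writeLines(as.character(mask$region_id), file.path(dir, "region_id.txt"))
  invisible(dir)
}

#' @rdname write_expression_grids
#' @export
read_expression_grids <- function(dir) {
  files <- list.files(dir, pattern = "__.*\\.nii\\.gz$", full.names = TRUE)
  if (length(files) == 0L) stop("no grid volumes found in ", dir)
  lab <- array(as.integer(round(RNifti::readNifti(file.path(dir, "mask.nii.gz")))),
               dim = dim(RNifti::readNifti(file.path(dir, "mask.nii.gz"))))
  region_id <- as.integer(readLines(file.path(dir, "region_id.txt"))[1])
  mask <- region_mask(lab, region_id)
  grids <- list()
  for (f in files) {
    stem <- sub("\\.nii\\.gz$", "", basename(f))
    parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
    vol <- RNifti::readNifti(f)
    gr <- expression_grid(array(as.numeric(vol), dim = dim(vol)),
                          gene_id = parts[1], experiment_id = parts[2])
    grids[[parts[1]]] <- c(grids[[parts[1]]], list(gr))
  }
  list(grids = grids, mask = mask)
}
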