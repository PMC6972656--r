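#' The default ontology category set
#'
#' The nine gene sub-categories used to restrict the enriched set to
#' classes of genes known to mark neuronal sub-populations: transcription
#' factors, cell communication, receptors, receptor activity, receptor
#' binding, transporters, transporter activity, signal transducer
#' activity and signalling molecules.
#'
#' @return ordered character vector of nine labels.
#' @export
default_categories <- function() {
  c("transcription factors", "cell communication", "receptors",
    "receptor activity", "receptor binding", "transporters",
    "transporter activity", "signal transducer activity",
    "signalling molecules")
}

#' Load a gene annotation table
#'
#' Reads a tab-separated annotation file with header columns `gene_id`,
#' `categories` (';'-separated labels, may be empty), `cre_available`
#' (0/1 or TRUE/FALSE) and `pattern_flag` (absent / mosaic / widespread /
#' unknown). Unknown pattern strings map to `"unknown"` with a warning;
#' duplicate gene ids and malformed booleans are errors.
#'
#' @param path file path.
#' @return annotation data.frame with a `categories` list column.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  need <- c("gene_id", "categories", "cre_available", "pattern_flag")
  if (!all(need %in% names(raw)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(raw$gene_id))
    stop("duplicate gene_id in annotations: ",
         paste(unique(raw$gene_id[duplicated(raw$gene_id)]), collapse = ", "))
  cre <- .parse_bool(raw$cre_available)
  if (any(is.na(cre)))
    stop("malformed cre_available value(s): ",
         paste(unique(raw$cre_available[is.na(cre)]), collapse = ", "))
  flag <- tolower(trimws(raw$pattern_flag))
  known <- c("absent", "mosaic", "widespread", "unknown")
  if (any(!flag %in% known)) {
    warning("unrecognized pattern flag(s) mapped to 'unknown': ",
            paste(unique(flag[!flag %in% known]), collapse = ", "))
    flag[!flag %in% known] <- "unknown"
  }
  cats <- lapply(raw$categories, function(s) {
    s <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    s[nzchar(s)]
  })
  out <- data.frame(gene_id = raw$gene_id, cre_available = cre,
                    pattern_flag = flag, stringsAsFactors = FALSE)
  out$categories <- cats
  out[, c("gene_id", "categories", "cre_available", "pattern_flag")]
}

.parse_bool <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("1", "true", "t"), TRUE,
  ifelse(x %in% c("0", "false", "f"), FALSE, NA))
}

#' Write an annotation table as TSV
#'
#' Inverse of [load_annotations()]; the `categories` list column is
#' ';'-joined.
#'
#' @param annotations annotation data.frame.
#' @param path output file.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(gene_id = annotations$gene_id,
                    categories = vapply(annotations$categories,
                                        paste, character(1), collapse = ";"),
                    cre_available = as.integer(annotations$cre_available),
                    pattern_flag = annotations$pattern_flag,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a gene set to ontology category members
#'
#' Keeps exactly the genes whose annotated category set intersects the
#' given categories (one shared label suffices). Genes missing from the
#' annotation table are treated as unannotated and excluded, with a
#' message giving their count.
#'
#' @param genes character vector of gene ids.
#' @param annotations annotation data.frame from [load_annotations()] or
#'   [simulate_annotations()].
#' @param categories character vector of category labels
#'   (default [default_categories()]).
#' @return character vector, a subset of `genes` (input order preserved).
#' @export
filter_by_categories <- function(genes, annotations,
                                 categories = default_categories()) {
  if (length(categories) == 0L) stop("category set must be non-empty")
  idx <- match(genes, annotations$gene_id)
  missing <- is.na(idx)
  if (any(missing))
    message(sum(missing), " gene(s) absent from the annotation table excluded")
  keep <- !missing & vapply(idx, function(i) {
    if (is.na(i)) FALSE else length(intersect(annotations$categories[[i]],
                                              categories)) > 0L
  }, logical(1))
  genes[keep]
}
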