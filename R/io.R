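# Tab-separated I/O for count matrices and sample sheets ('#' comments,
# UTF-8).

#' Write / read a count matrix and its sample sheet
#'
#' The counts TSV has a `gene_id` column followed by one column per
#' sample; the sample sheet TSV has columns `sample_id`, `group`,
#' `replicate`, and optionally the counts file carries gene lengths in a
#' side TSV (`gene_id`, `length_kb`).
#'
#' @param m a [count_matrix()].
#' @param counts_path,samples_path,lengths_path file paths;
#'   `lengths_path` optional.
#' @return `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(m, counts_path, samples_path,
                               lengths_path = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  tab <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(m$gene_length_kb)) {
    utils::write.table(data.frame(gene_id = names(m$gene_length_kb),
                                  length_kb = unname(m$gene_length_kb)),
                       lengths_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path,
                              lengths_path = NULL) {
  tab <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           comment.char = "#", check.names = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("counts TSV must start with a gene_id column")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               comment.char = "#")
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample sheet must have sample_id and group columns")
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample sheet and counts columns disagree")
  counts <- counts[, samples$sample_id, drop = FALSE]
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, stringsAsFactors = FALSE,
                            comment.char = "#")
    lengths <- stats::setNames(lt$length_kb, lt$gene_id)
  }
  count_matrix(counts, samples$group, gene_length_kb = lengths)
}
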