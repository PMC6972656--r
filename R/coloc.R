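# Immunolabelling co-localisation summaries: per-animal percentages with
# cross-animal mean and SEM, the quantities shown in the validation panels
# for each candidate marker.

#' Read a per-cell immunolabelling table
#'
#' CSV with header `cell_id, animal_id, candidate, ha, th`; label columns
#' are 0/1. Any other label value or a duplicated cell id within an
#' animal aborts with the offending line numbers.
#'
#' @param path file path.
#' @return `data.frame` of class `"cell_table"` with logical label
#'   columns.
#' @export
read_cell_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("cell_id", "animal_id", "candidate", "ha", "th")
  if (!all(need %in% names(raw)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  parse01 <- function(col) {
    v <- trimws(raw[[col]])
    bad <- which(!v %in% c("0", "1"))
    if (length(bad))
      stop("non-boolean value in column '", col, "' at data line(s): ",
           paste(bad, collapse = ", "))
    v == "1"
  }
  out <- data.frame(cell_id = raw$cell_id, animal_id = raw$animal_id,
                    candidate = parse01("candidate"), ha = parse01("ha"),
                    th = parse01("th"), stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("animal_id", "cell_id")])
  if (any(dup))
    stop("duplicate cell id within animal at data line(s): ",
         paste(which(dup), collapse = ", "))
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Write a cell table as CSV
#'
#' @param cells a cell table.
#' @param path output file; labels encoded 0/1.
#' @export
write_cell_table <- function(cells, path) {
  out <- data.frame(cell_id = cells$cell_id, animal_id = cells$animal_id,
                    candidate = as.integer(cells$candidate),
                    ha = as.integer(cells$ha), th = as.integer(cells$th),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Co-localisation summary of a cell table
#'
#' For each animal computes (i) the composition of candidate-positive
#' cells over the exclusive, exhaustive classes HA+ only, TH+ only,
#' HA+ and TH+, neither (percentages summing to 100), and (ii) the
#' percentage of HA+ cells and of TH+ cells that are candidate-positive.
#' Percentages are then averaged across animals with
#' `SEM = sd(animal means) / sqrt(n_animals)`. An animal without
#' candidate-positive cells is omitted from the composition means with a
#' warning; an empty HA+/TH+ denominator yields a flagged-missing (`NA`)
#' entry for that animal, never a zero.
#'
#' @param cells a cell table ([read_cell_table()] or
#'   [simulate_cell_table()]).
#' @return object of class `"coloc_summary"`: list with `per_animal`
#'   (long data.frame: animal_id, statistic, value, n_denominator) and
#'   `summary` (statistic, mean, sem, n_animals).
#' @export
summarize_colocalization <- function(cells) {
  if (nrow(cells) == 0L) stop("empty cell table")
  animals <- unique(cells$animal_id)
  if (length(animals) == 0L) stop("at least one animal is required")

  stat_names <- c("pct_candidate_ha_only", "pct_candidate_th_only",
                  "pct_candidate_both", "pct_candidate_neither",
                  "pct_ha_candidate", "pct_th_candidate")
  per <- lapply(animals, function(a) {
    d <- cells[cells$animal_id == a, ]
    cand <- d[d$candidate, ]
    n_cand <- nrow(cand)
    comp <- if (n_cand > 0) {
      100 * c(mean(cand$ha & !cand$th), mean(!cand$ha & cand$th),
              mean(cand$ha & cand$th), mean(!cand$ha & !cand$th))
    } else rep(NA_real_, 4)
    n_ha <- sum(d$ha); n_th <- sum(d$th)
    p_ha <- if (n_ha > 0) 100 * mean(d$candidate[d$ha]) else NA_real_
    p_th <- if (n_th > 0) 100 * mean(d$candidate[d$th]) else NA_real_
    data.frame(animal_id = a, statistic = stat_names,
               value = c(comp, p_ha, p_th),
               n_denominator = c(rep(n_cand, 4), n_ha, n_th),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  no_cand <- unique(per$animal_id[per$statistic == "pct_candidate_ha_only" &
                                    is.na(per$value)])
  if (length(no_cand))
    warning("animal(s) without candidate-positive cells omitted from the ",
            "composition means: ", paste(no_cand, collapse = ", "))

  summ <- do.call(rbind, lapply(stat_names, function(s) {
    v <- per$value[per$statistic == s]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(statistic = s,
               mean = if (n > 0) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n_animals = n, stringsAsFactors = FALSE)
  }))
  structure(list(per_animal = per, summary = summ,
                 n_animals = length(animals)),
            class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf("Co-localisation summary (%d animal(s))\n", x$n_animals))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (is.na(s$mean[i])) {
      cat(sprintf("  %-26s missing (empty denominator)\n", s$statistic[i]))
    } else {
      cat(sprintf("  %-26s %5.1f%% +/- %s (n = %d)\n", s$statistic[i],
                  s$mean[i],
                  if (is.na(s$sem[i])) "NA" else sprintf("%.1f", s$sem[i]),
                  s$n_animals[i]))
    }
  }
  invisible(x)
}

#' Write a co-localisation summary as TSV
#'
#' @param summary a [summarize_colocalization()] object.
#' @param path output file (full precision; one row per statistic).
#' @export
write_coloc_summary <- function(summary, path) {
  utils::write.table(summary$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
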