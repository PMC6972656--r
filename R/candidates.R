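#' The published candidate marker table
#'
#' The six immunolabelling-validated candidate markers of VTA GABA-neuron
#' sub-groups with their reported enrichment statistics (log2 fold change
#' of GABA-IP over dopamine-IP and BH-adjusted p-value) and the source of
#' an available cre-driver line.
#'
#' @return data.frame with columns `symbol`, `gene_name`, `function_note`,
#'   `log2fc`, `p_adj`, `cre_source`.
#' @export
candidate_table <- function() {
  data.frame(
    symbol = c("Gpr101", "Cbln4", "Rxfp3", "Rora", "Trh", "Nrp2"),
    gene_name = c("G protein-coupled receptor 101",
                  "Cerebellin 4 precursor",
                  "Relaxin/insulin-like family peptide receptor 3",
                  "RAR-related orphan receptor A",
                  "Thyrotropin-releasing hormone",
                  "Neuropilin 2"),
    function_note = c("Orphan G protein-coupled receptor",
                      "Small secreted protein",
                      "G protein-coupled receptor for relaxin-3",
                      "Nuclear hormone receptor",
                      "Hormone",
                      "Transmembrane receptor for semaphorin 3C"),
    log2fc = c(1.24, 1.28, 1.71, 1.10, 1.50, 0.42),
    p_adj = c(4.25e-06, 1.42e-05, 4.59e-05, 4.95e-04, 1.67e-03, 4.10e-02),
    cre_source = c("Reinius et al. (2015)", "MMRRC", "MMRRC",
                   "Wu et al. (2010)", "Sugrue et al. (2010)",
                   "Wiszniak et al. (2015)"),
    stringsAsFactors = FALSE)
}

#' The twelve-gene shortlist preceding the literature exclusions
#'
#' The genes that survived enrichment, ontology restriction, the 5-50%
#' mosaicism window, image inspection and the cre-line requirement:
#' the six validated candidates, Nos1 (a previously established
#' sub-population marker, retained as a positive control of the
#' approach), and the five genes subsequently removed on literature
#' grounds (see [default_exclusions()]).
#'
#' @return character vector of twelve gene symbols.
#' @export
shortlist_genes <- function() {
  c(candidate_table()$symbol, "Nos1", names(default_exclusions()))
}
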