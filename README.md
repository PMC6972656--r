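# mosaicscreen

Many brain regions contain neuronal populations — midbrain GABA neurons
among them — whose sub-groups lack molecular markers, leaving no genetic
entry point for targeting them. `mosaicscreen` is an R package for the
screen that finds such markers by combining two independent data types:

1. **cell-type-resolved expression profiles** from tagged-polysome
   immunoprecipitation (RiboTag-style GABA-IP vs dopamine-IP RNA-seq),
   tested for differential enrichment with a negative-binomial Wald
   test and Benjamini–Hochberg correction; and
2. **quantified regional in situ hybridisation volumes**, reduced to an
   *expression density* (fraction of region voxels expressing) that,
   normalised by a pan-population reference gene such as *Vgat*,
   estimates the *fraction of the population* expressing each gene.

Genes that are enriched in the population of interest, belong to
functional classes plausible for markers (nine ontology categories),
and are expressed **mosaically** — by between 5% and 50% of the
population, inclusive — survive a funnel of contracting filters
(ontology → window → expression pattern → cre-driver availability →
literature exclusions) whose stages are recorded in a nested ledger.
Validation by immunolabelling is summarised as per-animal
co-localisation percentages with cross-animal mean ± SEM.

For the enrichment model, gene $g$ in sample $j$ has NB counts with
mean $s_j\mu_{g,\text{group}(j)}$ and variance $\mu + \alpha\mu^2$;
size factors $s_j$ are median-of-ratios, the fold change is
$\log_2\!\big[(\bar y_{\text{GABA}}+c)/(\bar y_{\text{DA}}+c)\big]$
with pseudocount $c=0.5$, and gene-wise moment dispersions are
moderated toward a pooled estimate so the Wald test is calibrated at
three replicates per group (see the methods vignette,
`vignettes/mosaic-marker-screening.Rmd`).

A planted-truth synthetic-data generator reproduces every input the
pipeline consumes — count matrices, expression grids with a region
mask, annotation tables, per-cell label tables — so the whole screen is
testable end to end with no external data.

## Worked example

```r
library(mosaicscreen)

tt <- truth_table(
  gene_id = c("Gad2", "Slc32a1", paste0("cand", 1:3), paste0("bg", 1:45)),
  planted_log2fc       = c(2.5, 2.2, 3, 3, 3, rep(0, 45)),
  expressing_fraction  = c(1.2, 1.1, 0.15, 0.30, 0.45, rep(0.2, 45)),
  categories = c(list(character(0)), list(character(0)),
                 rep(list("receptors"), 3), rep(list(character(0)), 45)),
  dispersion = 0.05)
cfg <- sim_config(seed = 42)
inp <- simulate_inputs(tt, cfg, n_experiments = 3, distractor_rate = 0)

fit <- nb_enrichment(inp$counts)
fit
#> Negative-binomial differential enrichment
#>   contrast: GABA_IP vs DA_IP (3 vs 3 samples)
#>   50 genes tested at alpha = 0.05: 5 enriched, 0 de-enriched, 45 not significant
#>   pooled dispersion 0.07138, prior df 50

scr <- run_pipeline(inp$counts, inp$annotations,
                    list(grids = inp$grids, mask = inp$mask),
                    pipeline_config(seed = 42))
scr
#> Mosaic-marker screen
#> Prioritisation funnel
#>   tested                           50
#>   enriched                          5
#>   in_categories                     3
#>   in_window                         3
#>   mosaic_pattern                    3
#>   cre_available                     3
#>   candidates                        3
#> Candidates:
#>  symbol log2fc    p_adj fraction expression_density cre_available
#>   cand1   2.66 2.17e-14    0.149             0.0301          TRUE
#>   cand2   2.75 7.66e-16    0.297             0.0602          TRUE
#>   cand3   2.83 3.80e-17    0.449             0.0908          TRUE
```

All five genes planted with strong enrichment are detected; the two
pan-population markers (`Gad2`, `Slc32a1`, planted at fractions above
the reference) fall at the category/window stages, and the three genes
planted mosaically (fractions 0.15/0.30/0.45 of the population) come
through as candidates with their fractions recovered from the voxel
grids. Validation counts are summarised per animal:

```r
cells <- simulate_cell_table(0.4, 0.05, cells_per_animal = 500,
                             n_animals = 3, gaba_proportion = 0.4, seed = 42)
summarize_colocalization(cells)
#> Co-localisation summary (3 animal(s))
#>   pct_candidate_ha_only       81.5% +/- 2.1 (n = 3)
#>   pct_candidate_th_only       15.8% +/- 0.8 (n = 3)
#>   pct_candidate_both           2.8% +/- 1.7 (n = 3)
#>   pct_candidate_neither        0.0% +/- 0.0 (n = 3)
#>   pct_ha_candidate            40.5% +/- 0.5 (n = 3)
#>   pct_th_candidate             5.6% +/- 0.9 (n = 3)
```

The planted 40% of HA+ (GABA) cells expressing the candidate is
recovered at 40.5 ± 0.5%.

The published six-candidate table and the twelve-gene shortlist it came
from are available as inputs via `candidate_table()` and
`shortlist_genes()`; `apply_exclusions(shortlist_genes())` reproduces
the seven-gene final list (including *Nos1*).

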