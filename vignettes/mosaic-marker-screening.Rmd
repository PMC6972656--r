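---
title: "Screening for mosaically expressed neuronal markers: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for mosaically expressed neuronal markers: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscreen)
```

## The problem

Midbrain GABA neurons are heterogeneous, but few molecular markers
delineate their sub-groups, which blocks genetic access to them. One
productive strategy combines two independent measurements: cell-type
resolved expression profiles obtained by immunoprecipitating tagged
polysomes from Cre-defined populations (a GABA-IP against a dopamine-IP
contrast), and a quantified regional in situ hybridisation atlas that
shows, gene by gene, how much of a brain region expresses it. A gene
that is (i) enriched in the GABA-IP profile, (ii) of a functional class
plausible for a neuronal marker, and (iii) expressed by only a scattered
subset of the region's GABA population is a candidate marker of a
sub-group, to be confirmed by immunolabelling.

`mosaicscreen` implements this screen as a sequence of testable,
individually re-runnable operations, with a synthetic-data generator
that plants known ground truth so every stage can be validated without
any external download.

## Differential enrichment model

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_{g,\mathrm{group}(j)}$ and variance
$\mu + \alpha_g \mu^2$, where $s_j$ is a per-sample size factor and
$\alpha_g$ the gene's dispersion. Size factors are classical
median-of-ratios: the median, over genes positive in every sample, of
the count divided by the gene's geometric mean (`estimate_size_factors()`;
when no gene qualifies the function stops rather than silently falling
back to a pseudo-reference). The enrichment statistic is

$$\widehat{\mathrm{lfc}}_g = \log_2
\frac{\bar y_{g,\mathrm{num}} + c}{\bar y_{g,\mathrm{den}} + c},$$

with $\bar y$ the group means of size-factor-normalized counts and
$c = 0.5$ a pseudocount that keeps fold changes finite at zeros. The
Wald standard error comes from the NB variance model via the delta
method, and two-sided p-values from the normal reference, followed by
Benjamini–Hochberg adjustment. A gene is called *enriched* when
$p_{\mathrm{adj}} \le \alpha$ (inclusive, default $\alpha = 0.05$) and
$\widehat{\mathrm{lfc}} > 0$, *de-enriched* with a negative fold change,
*not significant* otherwise.

### Dispersion estimation and calibration

With three replicates per group, the raw gene-wise method-of-moments
dispersion $\hat\alpha_g = (s^2_g - \bar\mu_g)/\bar\mu_g^2$ (pooled
within-group variance, floored at $10^{-8}$) is extremely noisy, and
plugging it into the Wald statistic makes the test behave like a
$t$-statistic with about four degrees of freedom referred to a normal —
realized type-I error near 12% at a nominal 5%. `nb_enrichment()`
therefore moderates each gene-wise estimate toward a pooled across-gene
moment estimate
$\hat\alpha_0 = \sum_g (s^2_g - \bar\mu_g) / \sum_g \bar\mu_g^2$ with
prior weight `prior_df` (default 50, against the gene's own 4 residual
df). The test suite verifies the resulting calibration on a 5,000-gene
global null (3 vs 3, mean 100, dispersion 0.1): the realized type-I
error at $p_{\mathrm{raw}} \le 0.05$ falls within $[0.04, 0.06]$.
Setting `prior_df = 0` recovers the raw gene-wise estimator. No
empirical-Bayes shrinkage of fold changes, outlier filtering or
independent filtering is attempted; the estimator is deliberately a
simple, documented approximation to the heavier machinery practitioners
use on real data, and the package does not claim parity with such tools.

## Regional expression density and the population fraction

A quantified ISH volume is a 3-D grid of non-negative signal. Within a
region mask,

* **expression density** = (number of voxels with signal strictly above
  the detection threshold) / (number of region voxels), and
* **expression intensity** = mean signal of those expressing voxels,
  *undefined* (`NA`, never 0) when no voxel expresses.

Replicate experiments for a gene are combined by unweighted arithmetic
means (undefined intensities dropped; density always defined). Two
readings of the intensity denominator are conceivable; taking it as the
*count* of expressing voxels (their mean signal) is adopted, since the
alternative (dividing summed intensity by summed intensity) would make
the quantity identically 1. The detection threshold is configuration,
not inference: quantified atlases apply their own proprietary detection
step, and pre-summarized per-structure tables can be ingested directly
(`read_summary_table()`), bypassing voxel data entirely. The grid and
table pathways agree exactly on round-tripped data, which the tests
check.

Dividing a gene's density by that of a reference gene expressed in the
whole population of interest (a *Vgat*-like gene for GABA neurons)
yields the **population fraction** — the estimated fraction of that
population expressing the gene. Fractions above 1 indicate expression
beyond the population (multiple cell types). The **mosaicism window**
retains genes with fraction in $[0.05, 0.50]$, both bounds inclusive
("between 5% and 50%" is read inclusively; the choice is surfaced as
configuration, and fraction > 1 genes can never enter the window).

## The funnel

The screen is a sequence of contractions, each recorded in a
`funnel_ledger` that enforces nesting (a stage containing a gene absent
from its predecessor is an integrity error, never silently repaired):

1. tested universe → 2. enriched → 3. ontology categories →
4. mosaicism window → 5. mosaic pattern → 6. cre-driver available →
7. candidates after literature exclusions.

The ontology step keeps genes whose annotation intersects a configured
category set (default: nine functional classes — transcription factors,
cell communication, receptors, receptor activity, receptor binding,
transporters, transporter activity, signal transducer activity,
signalling molecules — the classes from which neuronal sub-group
markers have historically come). One shared label suffices;
unannotated genes are conservatively excluded with a logged count.

The pattern step defaults to *curated* flags, mirroring the manual
image inspection this decision requires in practice; genes with an
`unknown` flag are retained with a warning rather than silently
dropped. An automated proxy (`score_pattern_proxy()`: absent below a
density floor, widespread above the reference density, mosaic between)
is available but marked non-canonical in all provenance, because a
density-only rule cannot see widespread expression *outside* the
quantified region — exactly the judgement manual inspection
contributes.

Exclusions are a configured id → reason map (defaults: a pan-population
transcription factor, two genes with reported dopamine-neuron
expression, a glial marker, and a gene whose antibodies fail in the
region); every applied exclusion is logged with its reason.

## Co-localisation summaries

Immunolabelling validation counts cells per animal. For each animal,
candidate-positive cells are partitioned into the exclusive, exhaustive
classes HA+ only / TH+ only / both / neither (percentages summing to
100), and the percentage of HA+ cells and of TH+ cells expressing the
candidate is computed. The animal — not the image — is the unit of
replication: summaries report the cross-animal mean with
$\mathrm{SEM} = \mathrm{sd}/\sqrt{n_{\mathrm{animals}}}$. An animal
without candidate-positive cells is omitted from the composition means
with a warning, and an empty HA+/TH+ denominator yields a
flagged-missing entry, never a zero. Double-positive (HA and TH) cells
are reported as their own class rather than folded into either.

## What the synthetic generator emulates — and what it does not

`simulate_inputs()` drives four generators from one integer seed
(per-stage substreams at fixed offsets, so outputs are bit-identical
across runs and independent of stage order):

* **Counts**: NB draws under the variance model above; size factors
  uniform on `library_size_range` (default 0.7–1.3); defaults of 3
  replicates per group match the emulated study design.
* **Expression grids**: inside a ~10,800-voxel region mask (the inner
  box of a 30×30×20 grid), each voxel expresses independently with
  probability `expressing_fraction × reference_expressing_probability`
  (reference default 0.2); expressing voxels get log-normal signal
  around 10, background stays below the detection threshold of 1.
  Probabilities scaling above 1 are clipped with a provenance warning.
  A clustered variant grows blob-shaped expression with the same
  marginal density, since real mosaic expression is spatially textured.
* **Cell tables**: multinomial class assignment (HA-only/TH-only/both/
  neither; the double-positive class defaults to 2% of the HA
  population), then class-conditional candidate positivity.
* **Annotations**: true categories plus Bernoulli distractor labels.

The generator's i.i.d. voxels, independent genes, log-normal signal and
animal-homogeneous cell probabilities are idealizations: real atlas
volumes have registration error, spatial autocorrelation and
per-experiment staining variation; real count data have correlated
library composition effects and outliers; real counting has observer
variance. Passing tests therefore demonstrate the *arithmetic and
statistical correctness* of the pipeline under its stated model, not
robustness to those artefacts.

## Numerical choices and degenerate inputs

* "Expressing" is *strictly* above threshold; a voxel exactly at
  threshold does not express.
* Pseudocount 0.5 normalized counts; dispersion floor $10^{-8}$;
  dispersion 0 in the generator degenerates to Poisson.
* Reference gene with zero density is an error (the normalization is
  undefined), as is an empty region mask or a gene set that leaves
  median-of-ratios without a reference gene.
* Window bounds inclusive at both ends; `lo >= hi` is a configuration
  error.
* Undefined intensities propagate as flagged `NA`, never as 0.

## Test problem sizes and the deterministic regime

The suite exercises calibration at 5,000 null genes (3 vs 3), oracle
equivalence on hundreds of random instances per operation, and
end-to-end recovery on an 83-gene truth table over the default
10,816-voxel mask with 3 replicate grids per gene — sizes chosen so the
full suite documents the statistical claims while running in well under
a minute, scaled-down but structurally faithful stand-ins for
genome-scale data.

End-to-end *exact* recovery of the planted candidate set needs a regime
where every stochastic stage is effectively deterministic: planted
log2 fold changes of 3 at dispersion 0.05 put true effects ≈11 Wald
SEs from the null, and planted expressing fractions
{0.10–0.45} ∪ {0.02, 0.8, 1.2} keep every gene at least ~6 binomial SEs
from the window boundaries. A fraction planted exactly at a window edge
(e.g. 0.50) would flip membership with probability ~½ under any finite
mask — no seed-independent zero-error claim is possible there, which is
why the fixture avoids exact boundaries while the boundary semantics
themselves are tested deterministically on fixed tables.

## Known limitations

* The enrichment test is a simplified estimator; its calibration is
  demonstrated at the simulated conditions, not proven generally.
* The headline funnel is only as good as its inputs: curated pattern
  flags and annotation tables are trusted, not inferred.
* No image registration, section processing or read-level simulation;
  the pipeline begins at count matrices and quantified grids.
* Population fractions inherit the atlas's detection behaviour through
  the threshold; comparisons are only meaningful within one
  thresholding convention.
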