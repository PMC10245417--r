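# cellwise

Cell-composition estimation and confounding assessment for bulk brain
omics.

Bulk brain tissue is a mixture of neurons, astrocytes, microglia,
oligodendrocytes and endothelial cells, and the mixing fractions vary
substantially between individuals — and between neighbouring tissue
samples of the *same* individual. Any case–control omics analysis in
which cell composition differs between groups (the canonical example is
neuronal loss in Alzheimer's disease) will, unless adjusted, mostly
rediscover cell-type-specific signal rather than disease biology.
`cellwise` implements the estimators, the marker-derivation machinery
and the bias diagnostics needed to study this problem, together with a
multi-omic simulator in which the true composition of every sample is
known.

## What it computes

**Profile estimators.** For each cell type with marker features, the
estimate is the samples' score on the first principal component of the
marker submatrix, rescaled to [0, 1]:

- **MGP** (marker gene profiles) — `log2(CPM + 1)` expression of marker
  genes; tracks *whole-tissue* abundance, which includes the neuropil
  (dendrites, axons, synapses).
- **MSP** (marker site profiles) — `log2(CPM + 1)` H3K27ac
  reads-in-peaks at cell-type-assigned acetylation marker sites; tracks
  the *nuclear* fraction.
- **WGBS MSP** — methylation beta at cell-assigned marks, median-imputed,
  with the score flipped (`1 − rescaled`) because marker marks are
  hypomethylated in their cell type; nuclear fraction.
- **Reference-based proportions** — nonnegative least squares against a
  linear-scale signature matrix, renormalized to the simplex; the
  comparator class of estimator.

**Marker derivation.** Differential acetylation between sorted NeuN+
(neuron) and NeuN− (glia) populations with a self-contained negative
binomial GLM (log link, library-size offset, method-of-moments
dispersion, Wald test), DAR selection at |fold change| > 4 and
mean count > 1000, annotation of peaks to promoter-proximal windows
(TSS − 5 kb to the end of the 5′UTR, strand-aware), and reassignment of
DARs to specific cell types via expression marker genes with an
exclusivity-and-sign-concordance rule.

**Evaluation framework.** Pairwise estimate correlations with sample
exclusion, correlation-based hierarchical clustering of estimate
columns, PC–covariate association, case–control differential
acetylation under a ladder of composition adjustments (none /
within-group-shuffled / five-level ordered factor / continuous), and
bias statistics against cell-type reference contrasts and region sets
(directional overlap fractions, effect-size correlations).

## Worked example

```r
library(cellwise)

panel <- build_reference_panel(seed = 7)                     # reference signals
comp  <- draw_compositions(50, seed = 8)                     # ground truth
sim   <- simulate_study(comp, panel, seed = 9)               # omics bundle

# derive H3K27ac marker sites from simulated sorted-nuclei data
sorted  <- simulate_sorted_chip(panel, seed = 11)
ref_da  <- call_differential(sorted$counts, sorted$group)
sites   <- assign_marker_sites(filter_dars(ref_da),
                               annotate_peaks(panel$peaks, panel$genes),
                               panel$expr_markers)

# estimate composition and compare to truth
est <- msp(sim$bundle$rip_counts, sites)
truth <- composition_matrix(comp, "nuclear")
round(sapply(colnames(est), function(k) cor(est[, k], truth[, k])), 3)
#>          neuron       astrocyte       microglia oligodendrocyte
#>           0.985           0.968           0.923           0.968
#>     endothelial
#>           0.942
```

Every column of `est` spans exactly [0, 1]; the correlations above are
against the known nuclear proportions of the simulated samples — at
default noise the profile methods recover the true fractions with
r > 0.9 for all five cell types.

A full simulated study — marker derivation, all four estimators, the
adjustment-model ladder and the bias reports, written as TSV/BED with a
checksummed manifest — runs with:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "pipeline_out")
```

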