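---
title: "Estimating brain cell composition from bulk omics, and what confounds it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brain cell composition from bulk omics, and what confounds it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk brain tissue mixes five broad cell classes — neurons, astrocytes,
microglia, oligodendrocytes and endothelial cells — in proportions that
differ between individuals, between diagnostic groups, and even between
neighbouring dissections of one Brodmann area (grey/white matter ratio
alone moves the oligodendrocyte fraction a lot). When a disease changes
composition (severe neuronal loss in entorhinal-cortex Alzheimer's
disease is the motivating case), an unadjusted case–control differential
analysis of any bulk omics modality returns mostly cell-type-specific
features: regions acetylated in neurons look "hypoacetylated in
disease" simply because cases contain fewer neurons.

Two further structural facts matter and are built into everything this
package does:

1. **Modalities see different tissue fractions.** RNA-seq samples the
   whole homogenate, including the neuropil — the mass of dendrites,
   axons and synapses that carries neuron-attributed RNA but no nuclei.
   Chromatin (H3K27ac reads-in-peaks) and bisulfite methylation sample
   nuclei. Whole-tissue and nuclear estimates of "neuron content" are
   therefore different quantities and correlate imperfectly.
2. **Adjacent tissue samples differ.** Estimates derived from a
   neighbouring piece of tissue (the common practice of adjusting
   chromatin data with methylation-derived estimates from another
   extract) carry dissection-level noise that same-extract estimates do
   not.

## The estimators

All three profile methods share one core: given a cell type's marker
features, center (and unit-scale) each feature across samples, take the
samples' scores on the first principal component, orient the sign so
that a high score means high marker signal, and rescale to span exactly
[0, 1]. The sign-orientation rule (positive correlation with the
across-feature mean of the scaled marker signal, ties broken toward a
positive loading sum) removes the inherent sign ambiguity of an SVD, so
results are bit-reproducible.

- **MGP** uses `log2(CPM + 1)` expression at marker genes. CPM
  normalization is applied here for symmetry with the chromatin scores;
  the first-PC construction is invariant to any per-feature affine
  change, so the choice matters little beyond the log stabilization.
- **MSP** uses `log2(CPM + 1)` reads-in-peaks at acetylation marker
  sites derived from sorted-population differential acetylation (below).
- **WGBS MSP** uses methylation beta at cell-assigned marks. Missing
  entries (zero-coverage sites) are imputed with the across-sample
  median of the site *before* scaling; sites missing everywhere are
  dropped. Because marker marks are hypomethylated in their own cell
  type, the reported score is `1 −` the rescaled PC score.
- **Reference-based proportions** solve, per sample, a nonnegative
  least-squares problem against linear-scale signature columns and
  renormalize to the simplex. This is the stand-in for the
  reference-based estimator class; it is exact in the noiseless
  identifiable case and is used as a comparator, not as the method of
  interest.

Profile scores are *relative* (each cell type's score spans [0, 1]
across the cohort); only the reference-based method returns absolute
proportions. Correlation against truth is therefore the right recovery
metric for profile methods.

## Deriving acetylation marker sites

Marker sites are not assumed; they are derived the way a real analysis
would derive them:

1. **Differential acetylation** between sorted NeuN+ (pure neuronal) and
   NeuN− (glial mixture) reads-in-peaks, using the package's negative
   binomial GLM (below). Positive log2 fold change means
   neuron-hyperacetylated.
2. **DAR selection** at |fold change| > 4 *and* mean count > 1000, both
   strict inequalities.
3. **Annotation** of peaks to every gene whose window — 5 kb upstream of
   the TSS through the end of the 5′UTR, reflected on the minus strand —
   they overlap by at least one base. Coordinates are 0-based half-open
   throughout; windows clamped at zero are logged. Strand-awareness is a
   configurable choice (`strand_aware = FALSE` widens the window on both
   sides) because annotation conventions differ between tools.
4. **Reassignment**: a DAR becomes a marker site of cell type K only if
   *every* gene it annotates to is a K expression marker and its
   direction is concordant (neuron markers must be neuron-up, glial
   markers glia-up). DARs touching markers of two cell types, any
   non-marker gene, or no gene are dropped. Concordance is enforced to
   exclude anti-markers; exclusivity guarantees the resulting marker
   sets are disjoint.

Methylation marks are filtered analogously: multi-assigned sites are
dropped, as are sites with coverage below 10 in strictly more than 20%
of samples.

## The differential engine

A deliberately self-contained negative binomial GLM, because the
downstream logic needs only log2 fold change, p and FDR:

- log link, library-size offset (log column totals);
- per-feature dispersion by method of moments on the residuals of a
  Poisson fit, with a residual-degrees-of-freedom correction
  (`n/(n - p)`), floored at 1e-8;
- a second GLM fit at the fixed dispersion; Wald statistic on the group
  coefficient referred to a t distribution with `n - p` degrees of
  freedom; Benjamini–Hochberg FDR.

The df correction and the t reference matter: without them the test runs
visibly anticonservative at cohort sizes of 50–100. With them, the
empirical type-I error on 1000 null NB features at nominal 0.05 sits
near 0.04–0.06 (the acceptance script recomputes this every run).
Constant covariates are dropped with a warning; a design in which the
condition is collinear with covariates raises an error naming the
aliased columns rather than silently reporting nonsense.

## The simulator

The synthetic-data generator is first-class code, because every claim in
the package is validated against known truth.

**Compositions.** Per individual, the TS1 proportions are a Dirichlet
draw; TS2 (the adjacent sample) adds Gaussian noise on the centered
log-ratio scale (`adjacency_sd`, default 0.3) and renormalizes; case
individuals receive a log-ratio shift (`condition_shift`) before TS2 is
derived, so both samples of an individual share the disease effect.
Default alpha is (24, 12, 3, 12, 3): expected fractions 44/22/6/22/6%,
with a total concentration chosen so interindividual variability matches
immunohistochemistry-scale spread (roughly 15% CV for neurons, ~50% for
the rare types). A more diffuse Dirichlet makes the rare cell types
implausibly volatile, which distorts every downstream statistic.

**Neuropil.** Whole-tissue proportions add a neuropil weight to the
neuron coordinate and renormalize. The weight is log-normal per
individual (sd 0.5) with a smaller per-sample factor (sd 0.15), mean
`neuropil_weight = 1`. The individual-level variance is the mechanism
that decorrelates whole-tissue from nuclear estimates — a constant
weight would make the two fractions deterministic transforms of each
other and no modality split could exist; the shared individual component
is what keeps two adjacent samples of one individual similar in their
neuropil character. With `neuropil_weight = 0` the two variants
coincide exactly.

**Signals.** A reference panel assigns each cell type a mean signal per
gene/peak/methylation site, normalized so each cell type's expression
and acetylation columns sum to one (signals read as expected counts at
unit library size). Marker features exceed the other types by at least
`marker_fold` (8) times a U(2, 30) multiplier, and their off-target
signal is damped tenfold: curated cell-type markers are
tens-to-hundreds-fold specific, and that strong specificity is exactly
what keeps markers of rare types (microglia are ~10% of the NeuN−
pool) callable as |FC| > 4 DARs from sorted-population bulk.
Methylation marker sites are hypomethylated in their type (beta 0.10 vs
0.85). Marker peaks sit inside the promoter window of same-type marker
genes; background peaks are intergenic; region sets for the bias module
are the marker peaks ± 200 bp.

**Counts and betas.** Expression counts are negative binomial around
`lib_size × Σ_k p_whole(k) × signal(k, g)`; reads-in-peaks use
`p_nuclear`; `dispersion = 0` gives the Poisson limit. Default
dispersion 0.05 (~22% biological CV per feature). Bulk beta is the
convex combination of cell-type betas plus bounded Gaussian noise
(sd 0.02), coverage is Poisson(30), and beta is missing exactly where
coverage is zero (extra missingness at 5%). A configurable fraction of
*non-marker* peaks carries genuine condition effects that multiply case
means — so "disease biology" and "composition signal" are disjoint by
construction and every bias statistic has an unambiguous truth.

All randomness flows from one integer seed per generator call, consumed
in a documented stream order, so identical calls are bit-identical.

**What the simulator does not emulate.** Per-feature dispersions, GC or
length biases, correlated features within regulatory domains, realistic
genomic coordinates, batch structure, or read-level artifacts. Passing
tests on this generator shows the *logic* of the estimators and
diagnostics is right under the stated generative assumptions — not that
real tissue meets those assumptions.

## Study conditions used by the checks

The packaged checks simulate two studies: a 50-individual cohort with no
condition effect (estimator recovery, same-vs-adjacent agreement, the
modality clustering split) and a 100-individual case–control cohort with
severe neuronal loss (clr shift −1.2, about a halving of the neuron
fraction — terminal-disease scale) plus 5% genuine differential peaks at
|log2FC| = 0.8 (the confounding ladder). The larger cohort is used for
the ladder because the within-group-shuffled covariate inflates the
variance of the condition estimate; at small n that variance inflation —
not the adjustment logic — dominates the comparison. Feature counts
(500 genes, 600 peaks, 150 methylation sites) keep a full study under a
few seconds without changing any qualitative behaviour.

## The adjustment ladder

`fit_adjusted_da()` fits the case–control NB model under one of four
composition adjustments:

- **none** — nuisance covariates only;
- **shuffled** — a five-level ordered factor of the estimate permuted
  within condition groups: preserves the covariate's distribution and
  its group difference while destroying its sample-level information
  (the negative control);
- **ordered_factor** — the estimate discretized into five ordered
  levels (quantile bins by default; equal-width available — the
  discretization convention is a genuinely open choice and both are
  exposed);
- **continuous** — estimates entered as continuous covariates, with an
  optional log transform. When the covariates are true proportions the
  log scale is the correct one for a log-link count model (the
  generative mean is exactly log-linear in the proportions), and all
  five log-proportions are entered: on the log scale the simplex
  constraint is not a collinearity, and omitting one type leaves its
  marker peaks unadjusted.

On the confounded study the diagnostics order exactly as the design
predicts: the unadjusted and shuffled models put >80% of significant
hypo-in-case peaks in the neuron-up reference class and show a strong
negative effect-size correlation with the neuron-vs-glia contrast; the
ordered-factor adjustment attenuates both; true-proportion adjustment
removes the bias (fraction near zero) while retaining >90% sensitivity
for the genuinely differential peaks.

## Numerical and convention choices

- Coordinates are 0-based half-open internally and at the BED boundary;
  conversion to 1-based closed happens only inside `GRanges`.
- Quantile binning of estimates into ordered factors maps equal values
  to equal levels, so the conversion is monotone; heavy ties can reduce
  the number of realized levels.
- `rescale01` maps a constant vector to all zeros rather than erroring;
  profile estimators never produce this on non-degenerate input.
- Hierarchical clustering of estimate columns uses distance `1 − r` and
  average linkage (configurable); leaf order is deterministic given the
  column order.
- PC–covariate association fits one joint linear model per component
  (all variables together), reports per-coefficient p-values, and drops
  collinear columns with a warning recorded in the output.
- Pipeline stage seeds derive from the master seed by fixed small
  offsets; the output manifest records file checksums, the
  configuration hash and the seed.

## Known limitations

- Profile scores are relative; comparing cohorts processed separately
  requires a pooled rescaling decision (the pipeline pools).
- The NB engine is a desk-scale tool: no dispersion shrinkage across
  features, no weighting; it is not intended to replicate DESeq2/edgeR
  output numerically.
- The reference-based comparator assumes the signature is on the same
  linear scale as the mixture and has full column rank; violations
  error rather than warn.
- Stepwise selection by AIC inherits the usual instability of stepwise
  procedures; the false-inclusion rate under the null is the standard
  stepwise baseline and is documented by a test rather than asserted
  tightly.
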