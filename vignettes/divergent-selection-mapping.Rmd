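---
title: "Mapping height QTL with single-plant association scans and bulk segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping height QTL with single-plant association scans and bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscan)
```

## The experimental design this package models

`tailscan` is a toolkit for mapping quantitative trait loci in a
heterogeneous, open-pollinated crop population — the setting of a maize
landrace — using *unreplicated single-plant* phenotypes. The design it
targets has two coupled arms:

1. **Single-plant GWAS.** Individual plants from a random-mating
   population are grown in several plots over two seasons, phenotyped once
   each (height in cm), and genotyped at low depth by
   genotyping-by-sequencing (GBS). An ordinary fixed-effect association
   scan is run on the standardized phenotypes of all genotyped plants,
   with generation and selection regime as covariates and an iterative
   pseudo-QTN refinement.
2. **Bulk segregant analysis (BSA).** In the first season, the tallest
   ~5% of plants are selected in half of the plots and the shortest ~5%
   in the other half. Their open-pollinated offspring are grown the next
   season; the genotyped offspring of tall-selected and short-selected
   plots form two *in-silico bulks* whose allele frequencies are compared
   marker by marker with a two-sided Z test. Selection moves allele
   frequencies at height QTL (and everything linked to them), so
   frequency outliers corroborate GWAS hits at essentially no extra cost:
   the same genotyping serves both arms.

A SNP that is significant in the association scan *and* falls inside a
BSA region has two nearly independent lines of evidence behind it; the
`overlap_snps_regions()` report formalizes that corroboration.

Because the original field experiment cannot be re-run at desk scale, the
package carries a forward simulator (`sim_config()`,
`simulate_experiment()`) that reproduces the whole design with known
truth: founder haplotypes with landrace-like LD, additive QTL at a target
narrow-sense heritability, per-plot truncation selection, random mating
with recombination, and a depth-driven GBS observation model. Every
pipeline stage is tested against that truth.

## Models and procedures

### Phenotype standardization

Heights are standardized by a one-factor fixed-effect linear model on the
location-year cell (`lm(height ~ plot:year)` in effect); the residuals are
the response for both scans. With four plots and two years this is eight
cells; residuals sum to zero within each cell, which removes plot and
season effects but deliberately nothing else — single plants have no
replication to separate micro-environment from genetics.

### Heritability

Two estimators are provided:

* **GREML** (`greml_h2()`): the one-component model
  $y = X\beta + g + e$, $g \sim N(0, \sigma^2_g K)$,
  $e \sim N(0, \sigma^2_e I)$, with $K$ the genomic relationship matrix
  $ZZ'/m$ built from standardized dosages $(d - 2p)/\sqrt{2p(1-p)}$. The
  GRM is eigendecomposed once and the restricted likelihood is profiled in
  $\lambda = \sigma^2_g/\sigma^2_e$, maximized by a bounded search on
  $\log\lambda \in [-10, 10]$ (tolerance $10^{-6}$). This is exact for
  the single-component model; no iterative REML is needed. A flat profile
  (e.g. $K = I$) or an optimum at the search boundary raises a flag, and
  estimates are reported with their variance components. Generation and
  regime covariates are included by default; the estimate is similar
  without them in simulated data.
* **Realized (breeder's equation)** (`realized_h2()`): $h^2 = R/S$ with
  $S$ the selection differential (selected-parent mean minus population
  mean) and $R$ the response (offspring mean minus population mean, in a
  common environment). Estimates outside $[0,1]$ are clamped and the
  clamping is always reported. On single 96-plant samples this ratio is
  noisy and frequently clamps; it stabilizes over replicates, which is
  how the tests exercise it.

### The association scan

`glm_scan()` fits, per marker, ordinary least squares of the residual
height on (intercept, generation, regime, pseudo-QTNs, marker dosage) and
reports the two-sided $t$ test of the dosage coefficient. The scan is
computed by Frisch–Waugh–Lovell residualization, so a 768 × 300,000 scan
is a few matrix products. Markers collinear with the covariates get
$p = 1$ and a flag rather than an unstable estimate.

`pseudo_qtn_scan()` adds a simplified iterative multi-locus refinement:
markers passing the significance threshold are sorted by $p$, greedily
pruned so no two lie within `min_qtn_distance` (default 1 Mb) on one
chromosome, retained if adding them lowers the BIC of the joint model,
and carried into the next scan as covariates; a marker already in the set
is tested with itself removed. Iteration stops when the set stabilizes.
This captures the fixed-effect/pseudo-QTN idea of modern multi-locus
scans without replicating any specific published implementation's
internals (bin optimization, kinship substitution), which are out of
scope here. The significance gate on entry (p < alpha) keeps the set
empty under the null — a pure-BIC entry rule would admit the best of
$m$ null markers, since its $t^2 \approx 2\log m$ exceeds $\log n$.

Significance uses the fixed threshold $p < 10^{-5}$ with no further
multiple-testing correction: at roughly 300,000 markers this implies
fewer than three expected false positives genome-wide, and
`call_significant()` reports that expectation alongside the count.

### The bulk segregant scan

Reference-allele frequencies per bulk are estimated over non-missing
calls (`insilico_bulk_freq()`); the contrast is the pooled two-proportion
Z test

$$Z = \frac{\hat p_T - \hat p_S}
{\sqrt{\bar p(1-\bar p)\left(\tfrac{1}{m_T} + \tfrac{1}{m_S}\right)}},$$

with $\bar p$ the allele-count-weighted pooled frequency and $m$ the
informative allele counts ($\le$ 2 × bulk size). $Z^2$ is identical to
the Pearson chi-square of the corresponding 2×2 allele-count table, which
the tests verify to $10^{-9}$. Pooled-monomorphic markers get $Z = 0$,
$p = 1$. The variance is pooled, the normal approximation is used, and
there is no continuity correction.

Region calling follows the outlier-quantile convention: the threshold is
the empirical 99.5% quantile of the raw $-\log_{10} p$ values (the "0.5%
outliers"), a centered 15-SNP sliding mean smooths the profile within
chromosomes (truncated at ends, never crossing a boundary), and regions
are maximal runs of smoothed values above the threshold, merged when
separated by fewer than 15 markers, each required to contain at least one
raw outlier. The peak SNP is the smallest raw $p$ in the region (ties to
the leftmost). The ordering — threshold from raw values, runs from
smoothed values — reproduces distinct "significant marker" and "region"
counts.

Two operating characteristics of this design are worth knowing
(both are properties of the published procedure, not of this
implementation):

* Because the threshold is a quantile of the *observed* scan, it adapts
  to the signal. Regions emerge only when the number of markers carrying
  elevated signal stays below the outlier budget ($0.005\,m$), so the
  threshold sits in the null tail; a genome saturated with strong linked
  signal pushes the threshold into the signal itself and suppresses
  regions. Detection also degrades when few parents found the next
  generation ($\lesssim 100$), because drift then inflates the null
  genome-wide. The simulated designs in the tests use $\ge 2000$ markers
  and $\ge 2000$ plants per plot for this reason; the default design uses
  the full 5000.
* On low-depth GBS calls the Z test is anticonservative: at ~2× depth
  roughly half of covered heterozygotes are called homozygous, inflating
  the variance of frequency estimates beyond binomial. The
  outlier-quantile threshold absorbs this genome-wide inflation (it is a
  quantile of the same inflated distribution), but nominal p-values from
  `ztest_scan()` on raw low-depth calls should not be read at face value.
  The calibration tests therefore use true genotypes. Exact allele-count
  ties between equal-sized bulks additionally put an atom of mass
  ($\approx$ 0.03 at 192-plant bulks) at $p = 1$, visible in any
  uniformity diagnostic of the null distribution.

### Corroboration

`overlap_snps_regions()` matches significant GWAS SNPs to BSA regions
with inclusive boundaries on 1-based coordinates, and
`annotate_nearby_genes()` lists gene models whose span intersects a
150 kb window around each SNP (distance 0 marks "SNP in candidate"),
reading gene features from GFF3 via `rtracklayer`.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` reproduces the full design: founders split into
`n_plots` plots (default 4 × 5000), Generation-0 phenotypes, per-plot
truncation at the `selection_fraction` quantile (tall in the first half
of plots, short in the second), within-plot random mating to a same-sized
Generation-1, sampling of 96 plants per plot-generation, and GBS
observation of the sampled plants.

* **Founder LD.** Founder haplotypes are first-order Markov chains along
  the genetic map with allele correlation $\exp(-d/\texttt{ld\_range\_cM})$
  at distance $d$ cM (default range 1 cM, i.e. $r^2 = 0.5$ at ~0.35 cM —
  the scale expected for a population descended from a bottleneck of
  ~100 individuals). This is a phenomenological LD model, not a
  coalescent: it reproduces the feature that matters for the method
  (selection signal spans blocks of linked markers, so BSA regions can
  exist and span megabases) without modeling allele-age structure. With
  `founder_ld = NULL` founders are in exact linkage equilibrium, which
  the sampling-theory tests use.
* **Trait.** Strictly additive: height = 180 cm baseline + plot-year
  offset + $\sum_j d_{ij}\alpha_j$ + Gaussian noise, with the noise
  variance solved so that $\mathrm{Var}(G)/\mathrm{Var}(P)$ equals
  `target_h2` (default 0.75, the scale of single-plant height
  heritability in the motivating experiment). Effects are drawn
  $N(0, 2\,\text{cm}^2)$ over 40 QTL by default, or planted exactly via
  the `fixed` effect law. No dominance, no epistasis, no
  genotype-by-environment interaction.
* **Meiosis.** Gametes recombine between adjacent markers with the
  Haldane probability from the cM map; chromosomes assort independently;
  selfing is allowed during random mating (open pollination includes
  self pollen; with hundreds of parents the effect is negligible).
* **GBS observation.** Depth per individual-site is
  Poisson(`mean_depth`, default 2.01). Zero reads → missing; covered
  heterozygotes are called homozygous when all reads carry one allele
  (probability $2^{1-d}$, split evenly), homozygotes are always called
  correctly; no sequencing error beyond that, since no error rate is
  available to calibrate one. Per-marker summed depths provide the
  read-count filter input.
* **Genome scale.** The default genome (5 chromosomes × 400 markers ×
  200 Mb) is a desk-scale stand-in chosen so that simulations complete in
  seconds-to-minutes while preserving the ratios that drive the method:
  marker spacing below the LD range, smoothing windows inside LD blocks,
  and an outlier budget ($0.005\,m$) above the per-QTL cluster size.
  Passing tests on this genome demonstrate the machinery and its
  calibration, not field-scale power; absolute marker counts (306k/243k)
  and the published region tally are functions of the real data and are
  not reproduced here.

Determinism: every stochastic stage draws its seed from the master seed
via `derive_seeds()`; the same configuration and seed give bit-identical
outputs, and the pipeline echoes config and seed next to its results.

## Numerical choices and degenerate inputs

* Marker filtering keeps MAF exactly 0.05 (exclusion is strict "< 0.05")
  and total read count exactly 40; "read count" is interpreted as the
  per-marker sum over samples, written as INFO `DP` in simulated VCFs.
  MAF is computed on non-missing calls. Filtering is idempotent.
* Missing dosages are imputed by the marker mean (real-valued
  thereafter); haplotype-aware imputation is intentionally out of scope,
  so downstream effects are per alt-allele-copy on fractional dosages.
* Truncation thresholds are type-7 empirical quantiles per plot;
  selection is inclusive of the threshold value, so `fraction = 1`
  selects every plant.
* The GREML search treats eigenvalues below zero (to tolerance) as zero;
  h² estimates from R/S are clamped to [0, 1] with a message, never
  silently.
* The outlier threshold uses the type-7 quantile; on 1000 distinct values
  at q = 0.005 exactly 5 lie strictly above it.
* The smoothing window must be odd (the center is undefined otherwise);
  15 is the field convention.
* Genomic inflation is reported as
  $\lambda = \mathrm{median}(\chi^2)/0.4549$ (the
  `qchisq(0.5, 1)` convention).
* Region gap-merging (default 15 markers) is exposed in configuration:
  no published merge rule exists, yet multi-megabase regions imply one.

## Known limitations

* The pseudo-QTN loop is a documented simplification, not a reimplementation
  of any specific multi-locus scan; its value here is absorbing
  large-effect loci so secondary signals surface.
* The BSA model is purely in-silico bulks of individually genotyped
  plants; DNA-pooled sequencing (read-level bulks) and alternative
  statistics (G-statistic, SNP-index deltas) are not modeled.
* Single-component GREML only: no GxE or multi-kernel variance models,
  and standard errors are not derived from likelihood curvature.
* The simulator models one cycle of selection and mating, without
  mutation, dominance, epistasis, or spatial field structure; its LD
  model is phenomenological (see above).
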