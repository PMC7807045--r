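---
title: "Models and methods behind epiRemodel"
author: "epiRemodel maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiRemodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

epiRemodel re-implements, as a tested and reusable toolchain, an
integrative analysis of chromatin-mark remodelling in brain tissue across
cell types, genotype and age: broad-domain (island) detection on binned
ChIP-seq coverage, count-based differential enrichment, classification of
neuronal versus glial enhancers from sorted-nuclei (NeuN+/NeuN-) data,
age-by-genotype concordance statistics, gene-body epigenetic metaprofiles
with k-means clustering and enrichment tests, 4C-seq fragment maps,
normalization and interaction calling, and 4C-derived 3D bead models with
virtual Hi-C matrices, insulation scores and TAD-boundary comparison.

Deposited sequencing data are deliberately out of scope: every stage is
validated against a seeded synthetic-data generator with planted ground
truth, small enough that the full test battery runs on a laptop in a few
minutes. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

# The synthetic study generator

`simulationConfig()` fixes the emulated study conditions. The defaults
are:

* **Genome**: 2 chromosomes of 5 Mb, tracks binned at 200 bp. Large
  enough for stable genome-wide island statistics, small enough that an
  island call takes well under a second.
* **Annotation**: 400 genes (2-6 kb); 120 neuronal, 120 glial and 60
  shared enhancers of 2 kb, each placed 1-3 kb upstream of its host
  gene's TSS on a randomized non-overlapping grid. Hosts inherit the
  enhancer's class; the remaining 100 genes are unclassed.
* **Signal model**: background 5 expected reads per bin; marked bins
  (class-matching enhancers and gene bodies, emulating broad
  super-enhancer-like domains) at 4-fold enrichment. NeuN+ nuclei carry
  H3K27ac at neuronal/shared features and H3K27me3 at glial gene bodies;
  NeuN- mirrors this. Bulk tissue is the mixture
  `0.55 * NeuN+ + 0.45 * NeuN-`; the NeuN+ fraction is identical across
  genotypes, matching the observation that neuronal/glial proportions do
  not differ between disease and wild-type striatum at these ages.
* **Planted effects** (log2, applied multiplicatively on the affected
  enhancer class only): genotype at the early age -0.7 (neuronal) / +0.7
  (glial), at the later age -1.2 / +1.2, age effect -1.0 / +1.0. The sign
  structure (neuronal depleted, glial enriched, concordant with age) and
  the progressive amplitude are constraints enforced by the
  `SimulationConfig` validity method — configurations violating them are
  rejected.
* **Noise**: negative-binomial counts with dispersion 0.05 and per-track
  library factors drawn from (0.8, 1.2). Dispersion 0 produces
  deterministic expectation tracks, which the noise-free identity tests
  rely on. NB rather than Poisson noise is used so the differential
  stage's dispersion handling is genuinely exercised.
* **RNA coupling**: a gene's true expression log2FC is
  `r * e + (1 - |r|) * noise` with `e` its enhancer's planted effect and
  `r = 0.8`; `r = 1` with zero noise reproduces the enhancer effects
  exactly and `r = 0` decouples transcription from chromatin, which the
  null-coupling test exploits.

No quantitative effect sizes for such a design are published; the values
above were chosen once as typical of strong cell-type-specific enhancer
signal in brain ChIP-seq and are exposed in the configuration rather than
hard-coded.

What the generator does **not** emulate: mappability and GC bias,
read-level artefacts, fragment-length effects, diploid genotypes,
CAG-repeat instability, and realistic correlation structure between
neighbouring regions. Passing the recovery tests therefore shows the
algorithms are correct and calibrated under the declared noise model; it
does not certify performance on arbitrary real libraries.

# Island calling

Windows of 200 bp are scored against a global Poisson background
`lambda` (total reads / windows; from a depth-scaled control track when
one is supplied). A window is *eligible* when its Poisson upper tail is
below `eligibility_p = 0.05`; islands are maximal runs of eligible
windows in which consecutive eligible windows are separated by at most
`gap` of ineligible sequence (per-mark defaults: 1000 bp for H3K27ac,
600 bp for RNAPII, 1400 bp for H3K27me3; window 200 bp; E-value 0.003).
The island score is the sum of `-log P(count; lambda)` over eligible
member windows.

Score significance is controlled by the expected number of false islands
genome-wide (the E-value). The null is Monte-Carlo: eligible windows are
scattered uniformly over the concatenated genome with the background
eligibility probability, their counts drawn from the background Poisson
tail, and null islands assembled under the same gap rule. Two numerical
choices matter:

* The null samples the *fitted background model* rather than permuting
  the observed window counts. On a genome where a substantial fraction
  of windows is genuinely enriched (the default synthetic genome has
  ~18% of its length under planted domains), a permutation null mixes
  signal windows into the null assembly and inflates the score threshold
  several-fold, silently destroying sensitivity; model-based sampling is
  identical to permutation on signal-free tracks and remains honest under
  dense signal.
* With `B` Monte-Carlo rounds the smallest resolvable expected count is
  `1/B`, so the default 20 rounds cannot express an E-value of 0.003.
  The round count is raised automatically to `ceiling(1/evalue)` whenever
  `B * evalue < 1`.

The analytic aggregate-score null of the original broad-domain caller is
under-documented; the seeded Monte-Carlo construction controls the same
quantity and is directly testable (on Poisson-null genomes the observed
false-island rate is checked against the E-value in the acceptance
suite).

# Differential enrichment

One engine serves every contrast. Per region it computes group means of
size-factor-normalized counts, a log2 fold-change with pseudocount 0.5,
and either of two tests:

* **NB Wald (`dispersion = "moments"`)** — per-region method-of-moments
  dispersions are shrunk toward a parametric `a0 + a1/mu` trend fitted
  across regions, with a prior weight of 40 residual-df equivalents. The
  Wald variance is computed on normalized counts,
  `(1/(mu + 0.5) + alpha)/n` per group, so declaring a rescaled sample
  through its size factor leaves every p-value unchanged at machine
  precision — a property the tests assert. The strong shrinkage is what
  makes the test calibrated at ChIP-seq-scale replication (2-4 per
  group): with 10,000 null NB regions at dispersion 0.05, the raw
  p < 0.05 rate stays inside 0.05 +/- 0.01 while a planted 2-fold effect
  at n = 3 vs 3 is detected with >= 90% power at BH 0.05.
* **Exact conditional (`dispersion = 0`)** — given the two groups'
  summed raw counts, the second group's total is binomial with the
  size-factor proportion, tested two-sided by minimum-likelihood
  enumeration. This is the Poisson framework in which the very stringent
  published-style thresholds (genotype FDR < 1e-5, cell-type contrast
  p < 1e-15) are meaningful: an NB Wald statistic at n = 2 per fraction
  is bounded far above such p-values no matter how strong the signal, so
  the enhancer-catalogue contrast defaults to the exact mode.

Size factors equalize background regions: the median across background
regions of (count / geometric mean across samples), normalized to
geometric mean 1, computed on the ratio scale exactly as stated. Sexes
are pooled per contrast (sex and batch are confounded in the emulated
design); a covariate hook exists but defaults off.

The two-sided binomial test is implemented in-package by full enumeration
under the minimum-likelihood convention (all outcomes whose point
probability does not exceed the observed one), without the small relative
tolerance the base implementation applies when detecting ties — the
acceptance contract requires exact equality with enumeration. The base
implementation serves as an independent cross-check away from ties.

# Integration statistics

* **Attribution**: a differential region overlapping (>= 1 bp) only
  neuronal catalogue entries is Neuronal, only glial entries Glial, and
  otherwise Non-specific; a region touching both classes is deliberately
  Non-specific (ambiguity rule). Both the overlap floor and the ambiguity
  rule are exposed as arguments since no published convention exists.
* **Metaprofiles**: coverage (1x-normalized, so a uniform track is
  identically 1) is resampled by exact piecewise-constant integration
  onto 2-kb flanks at 100 bp/bin plus 100 length-scaled gene-body bins
  (gene scheme) or a fixed window on region midpoints (region scheme),
  strand-flipped so bin 1 is 5'. The bin counts are package choices; the
  upstream tool they echo does not document its own.
* **k-means**: profiles for H3K27ac and H3K27me3 in both fractions are
  concatenated per gene (a flag allows single-matrix clustering, since
  the published analysis does not state which was used) and clustered
  with seeded k-means++ initialization, best of 5 restarts by within-
  cluster sum of squares; k = 7 by default, deterministic under a fixed
  seed.
* **Enrichment tests**: cluster membership of top-N dysregulated genes
  (both p and adjusted-p ranking supported; ties broken lexicographically
  by gene id for determinism), neuronal-vs-glial specificity of top
  genes, and per-chromosome DEG concentration all use the two-sided
  exact binomial against the universe share, Bonferroni-adjusted where a
  family is reported. On the 400-gene synthetic universe the top-N
  default is scaled to 100.
* **Concordance**: regions with raw p < 0.05 in both the genotype and
  age contrasts are retained, attributed, and summarized by per-label
  mean log2FCs, sign-concordance fractions and Spearman's rho; the
  z-score heatmap rows are ordered by average-linkage Euclidean
  hierarchical clustering (deterministic, no seed).
* **Group z-score comparisons** pool gene-wise z-scores per group and use
  the Kruskal-Wallis chi-square tail with tie correction ("one-sided"
  KW wording in the emulated analysis is non-standard; the standard tail
  is used) with BH-adjusted pairwise Wilcoxon follow-ups. Constant
  expression rows z-score to zero with a warning rather than NaN.
* **Nuclear fractions** follow the printed formula
  `NeuN+% = NeuN+ / (NeuN+ + NeuN-) * 100`, warning below 30,000 total
  events.

# 4C-seq

Fragment maps assign the 4-bp first-cutter site to its downstream
fragment (the enzyme cuts 5' of the site), annotate second-cutter
presence, and flag blind fragments. Bait design applies the two strict
distance criteria (> 350 bp to the consecutive second-cutter site;
fragment length strictly between 500 and 1500 bp).

Profiles are quantile-normalized across samples over scored fragments
(bait +/- 2 fragments are excluded as self-ligation/undigested
artefacts; configurable) and smoothed by a centred running mean of 21
fragments with shrunken symmetric edge windows.

Interaction calling fits, per sample and per side of the bait, an
isotonic (monotone non-increasing with distance) background to the
smoothed log-scores — log because 4C noise is multiplicative, so raw
residual spread would grow toward the bait and bait-proximal false calls
would recur in every sample. The exceedance threshold is scale-free and
self-exempting: the noise spread is estimated from trimmed first
differences of the residuals (a broad genuine interaction cannot inflate
its own threshold), rescaled by the smoothing factor, and Sidak-corrected
over the effective number of independent smoothing windows so that a null
profile rarely yields any candidate. Candidates within 2 fragments merge;
regions need >= 3 fragments; reproducible regions are intersected extents
across all samples of a condition. On 100 seeded runs a planted 10-
fragment contact at 3x background is recovered >= 95% of the time and
monotone-decay nulls stay clean in >= 95%.

Differential interactions compare per-sample region means by two-tailed
t-tests (paired when declared; zero-variance paired differences fall back
to unpaired Welch with a warning), BH-adjusted across regions. The
published region-level p-values on the deposited data are not
reproducible at desk scale and are not targeted.

# 3D models, virtual Hi-C and insulation

Per (bait, bead), the bead signal is the mean of member-fragment scores
and the restraint distance is the inverse-power transform
`d ~ s^(-1/alpha)` (alpha = 1). By default the transform is rescaled
*proportionally* (largest value mapped to `dMax` = 10 model units),
which is exact for a true power-law contact model; the affine variant
(both ends of the range pinned) is available but introduces an additive
offset that distorts noise-free round trips. Distances are arbitrary
model units throughout: 4C signal fixes no physical scale, so only
relative geometry is interpreted and model comparisons use
reflection-invariant quantities (distance matrices; Procrustes with
reflection allowed in the tests).

The model minimizes squared restraint violations plus harmonic
connectivity walls on consecutive beads and a soft excluded-volume lower
wall on non-adjacent pairs, by L-BFGS-B from seeded random-walk
initializations (default 20 restarts; wall bounds scale with the typical
consecutive-bead spacing implied by the restraints). The original
modelling tool's simulated-annealing engine and force constants are not
published; the contract here is objective minimization, verified by
recovering exactly satisfiable collinear systems to 1e-3 and planted
geometries to Spearman >= 0.9 on the all-pairs distance matrix with only
2 restarts.

Insulation uses the contact proxy `1/(d + eps)` with
`eps = 1e-6 * median(d)` — on a distance model this form makes "low
insulation at boundaries" literally true. For window sizes b = 4..30
beads (capped below half the chain) the insulation at position k is the
mean contact over the b x b square crossing k, defined only where the
window fits; each scale is z-scored and the aggregate averages the scales
over their common support. Boundaries are local minima of the aggregate
with prominence >= 0.2 of its range; whether the original analysis called
minima per scale or on the aggregate is not stated, so the aggregate is
used and the per-scale matrix retained. Boundary comparison matches
greedily by proximity and reports signed displacement (beads and bp) and
insulation-depth differences; a planted 2-bead boundary shift is
recovered within +/- 1 bead.

# Problem sizes and determinism

The default validation battery uses: 2 x 5 Mb genomes (50 Poisson-null
seeds for the island E-value check), 10,000 null NB regions for
calibration, 100 random 10-kb sequences for fragment maps, 100 seeded
4C profile pairs of 300 fragments, and 40-bead chains with 5 baits for
the 3D stage. These sizes were chosen so that each stage's statistical
property is measured with useful precision while the whole battery
completes in minutes. Every stochastic step takes an explicit seed and
the byte-determinism of all writers under a fixed seed is itself a test.

# Known limitations

* The island caller consumes binned counts; read-level processing
  (alignment, redundancy filtering, fragment-shift estimation) is
  upstream and out of scope, as is exact reproduction of the original
  tool's outputs.
* The NB engine is a single two-group contrast engine; it has no GLM
  covariates, shrinkage of fold-changes, or outlier refitting.
* The interaction caller implements the contract of the published
  approach (monotone background, per-sample calls, cross-sample
  reproducibility), not its exact statistic.
* Whether the stringent cell-type cutoff applies to raw or adjusted
  p-values is not stated in the emulated analysis; raw is the default
  with a flag to switch.
* Bead models inherit the usual 4C-to-3D caveats: per-bait amplitudes
  are assumed shared, and geometry is identifiable only up to rotation,
  reflection and global scale.
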