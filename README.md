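# epiRemodel

Integrative analysis of cell-type-resolved chromatin remodelling in brain
tissue, for epigenomics researchers studying how disease mutations
interact with ageing at neuronal and glial regulatory elements.

The package provides a complete, tested toolchain for the kind of study
that profiles striatal H3K27ac/H3K27me3/RNAPII ChIP-seq across genotype
and age, classifies enhancers by cell type from sorted-nuclei
(NeuN+/NeuN−) data, integrates them with transcriptomics, and probes 3D
chromatin architecture with multi-bait 4C-seq:

* **Island calling** — SICER-style broad-domain detection on binned
  coverage: windows are eligible when their Poisson upper tail
  P(X ≥ c; λ) < 0.05, islands are gap-tolerant runs of eligible windows
  scored by Σ −log P(count; λ), retained under genome-wide E-value
  control (defaults: window 200 bp; gap 1000/600/1400 bp for
  H3K27ac/RNAPII/H3K27me3; E = 0.003).
* **Differential enrichment** — one negative-binomial Wald engine with
  trend-shrunken method-of-moments dispersions, whose `dispersion = 0`
  mode degenerates to the exact conditional Poisson (binomial) test;
  background-equalizing median-of-ratios size factors; the NeuN+ vs NeuN−
  contrast at p < 1e−15 defines the neuronal/glial enhancer catalogue.
* **Integration** — cell-type attribution of differential regions,
  gene-body metaprofiles (scaled TSS→TTS bins plus flanks), k-means
  epigenetic clustering (k = 7, seeded k-means++), two-sided exact
  binomial enrichment of top dysregulated genes per cluster / cell type /
  chromosome, age-by-genotype concordance with Spearman's ρ, and
  Kruskal–Wallis group comparisons of expression z-scores.
* **4C-seq** — GATC/GTAC restriction-fragment maps, bait-design checks,
  quantile normalization, 21-fragment running-mean smoothing,
  isotonic-background interaction calling with cross-sample
  reproducibility, and paired/unpaired differential interaction t-tests.
* **3D models** — distance restraints d ∝ s^(−1/α) from multi-bait 4C
  signal, restrained distance-geometry optimization into bead models,
  virtual Hi-C distance matrices, multi-scale insulation scores
  (windows of 4–30 beads) and TAD-boundary detection/comparison.

A seeded synthetic-data generator (`simulationConfig()`,
`simulateGenomeAnnotation()`, `simulateChipTracks()`, `simulateRnaseq()`,
`simulateFourC()`, `plantedTadGeometry()`) plants ground truth —
cell-type-structured enhancers, progressive genotype effects concordant
with age, coupled transcription, two-TAD bead geometries — so every stage
has a parameter-recovery test.

## Worked example

The whole integrative analysis runs on a simulated study with one call:

```r
library(epiRemodel)
res <- runStudyPipeline(simulationConfig(seed = 11))

lab <- S4Vectors::mcols(res$attribution$regions)$celltype_label
dir <- S4Vectors::mcols(res$attribution$regions)$direction
table(dir, lab)
res$concordance$spearman
res$enrichmentDown[res$neuronalCluster, ]
```

On this seed the pipeline calls 463 high-confidence H3K27ac regions and a
443-entry enhancer catalogue, and reports:

```
         label
direction Glial Neuronal Non-specific
     down     0       35            0
     up      79        0            1
genotype x age Spearman rho = 0.93 (p < 1e-15)
neuronal-archetype cluster: 55/100 top-down genes (expected 17.5),
Bonferroni p = 2.1e-16
```

Read: regions losing H3K27ac under the disease genotype are almost all
neuronal-specific enhancers and regions gaining it glial-specific; the
genotype effect is strongly concordant with the age effect (accelerated
ageing); and the most downregulated genes concentrate in the k-means
cluster whose centroid carries the neuronal super-enhancer signature
(high NeuN+ H3K27ac, high NeuN− H3K27me3) — recovering the planted
structure of the simulation.

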