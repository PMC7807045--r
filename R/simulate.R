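#' Build a simulation configuration
#'
#' Defaults encode the emulated study conditions: a 2 x 5 Mb genome binned at
#' 200 bp, cell-type structured enhancers attached to host genes, genotype
#' effects that deplete neuronal enhancers and enrich glial enhancers with
#' larger amplitude at the later age, a concordant age effect, negative
#' binomial count noise (dispersion 0.05), and a NeuN+ bulk mixture fraction
#' identical across genotypes.
#'
#' @param seed integer RNG seed
#' @param genome named chromosome lengths in bp
#' @param binSize track bin width in bp
#' @param nGenes number of genes
#' @param enhancerPlan data.frame(class, n, width)
#' @param effectPlan data.frame(class, genotypeAge1, genotypeAge2, age) of
#'   log2 effect sizes
#' @param dispersion NB dispersion of ChIP counts
#' @param libRange relative library-size range
#' @param mixture NeuN+ fraction of bulk tissue
#' @param backgroundMean expected background reads per bin
#' @param enhancerFold fold-enrichment of marked bins over background
#' @param rnaCoupling coupling weight between enhancer and mRNA log2 effects
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(
    seed = 1L,
    genome = c(chr1 = 5e6, chr2 = 5e6),
    binSize = 200L,
    nGenes = 400L,
    enhancerPlan = data.frame(
      class = c("neuronal", "glial", "shared"),
      n = c(120L, 120L, 60L),
      width = c(2000L, 2000L, 2000L)),
    effectPlan = data.frame(
      class = c("neuronal", "glial", "shared"),
      genotypeAge1 = c(-0.7, 0.7, 0),
      genotypeAge2 = c(-1.2, 1.2, 0),
      age = c(-1.0, 1.0, 0)),
    dispersion = 0.05,
    libRange = c(0.8, 1.2),
    mixture = 0.55,
    backgroundMean = 5,
    enhancerFold = 4,
    rnaCoupling = 0.8) {
  new("SimulationConfig", seed = as.integer(seed), genome = genome,
      binSize = as.integer(binSize), nGenes = as.integer(nGenes),
      enhancerPlan = enhancerPlan, effectPlan = effectPlan,
      dispersion = dispersion, libRange = libRange, mixture = mixture,
      backgroundMean = backgroundMean, enhancerFold = enhancerFold,
      rnaCoupling = rnaCoupling)
}

#' Simulate a genome, gene annotation and planted enhancer truth
#'
#' Genes and their attached enhancers are placed on a randomized
#' non-overlapping grid (uniformly sampled slots), each enhancer 1-3 kb
#' upstream of its host gene's TSS on the gene's strand. The first
#' \code{sum(enhancerPlan$n)} genes (in random order) host one enhancer each
#' and inherit its class; remaining genes carry class \code{none}. Optionally
#' generates random genome sequence with first/second-cutter sites planted at
#' a configurable density (on top of the sites arising by chance).
#'
#' @param cfg a \linkS4class{SimulationConfig}
#' @param withSequence also generate genome sequence (DNAStringSet)
#' @param siteEvery approximate planted spacing (bp) of GATC/GTAC sites
#' @return list with \code{genes} (GRanges: gene_id, tss, tts, class),
#'   \code{enhancers} (GRanges: class, hostGene and per-contrast log2
#'   effects), \code{seqlengths}, \code{genome} (DNAStringSet or NULL) and
#'   \code{cfg}
#' @export
simulateGenomeAnnotation <- function(cfg, withSequence = FALSE,
                                     siteEvery = 400) {
  withSeed(cfg@seed, function() {
    sl <- cfg@genome
    nEnh <- sum(cfg@enhancerPlan$n)
    if (nEnh > 0 && sum(cfg@enhancerPlan$n * cfg@enhancerPlan$width) >
          sum(sl))
      stop("infeasible packing: requested enhancer bp exceeds genome bp")
    maxGene <- 6000; maxEnh <- max(c(cfg@enhancerPlan$width, 0))
    slotWidth <- maxGene + maxEnh + 5000 + 2000
    slotsPerChr <- floor(sl / slotWidth)
    if (sum(slotsPerChr) < cfg@nGenes)
      stop("infeasible packing: genome too small for requested genes")
    slotChr <- rep(names(sl), slotsPerChr)
    slotOff <- unlist(lapply(slotsPerChr,
                             function(k) (seq_len(k) - 1) * slotWidth),
                      use.names = FALSE)
    if (cfg@nGenes == 0L) {
      genes <- GRanges()
      enhancers <- GRanges()
    } else {
      pick <- sample(length(slotChr), cfg@nGenes)
      geneWidth <- round(runif(cfg@nGenes, 2000, maxGene))
      strandG <- sample(c("+", "-"), cfg@nGenes, replace = TRUE)
      enhClass <- rep(cfg@enhancerPlan$class, cfg@enhancerPlan$n)
      enhWidth <- rep(cfg@enhancerPlan$width, cfg@enhancerPlan$n)
      if (nEnh > cfg@nGenes)
        stop("enhancer plan requests more enhancers than genes")
      geneClass <- c(enhClass, rep("none", cfg@nGenes - nEnh))
      gap <- round(runif(cfg@nGenes, 1000, 3000))
      ## layout within slot (plus strand): [enh][gap][gene]; mirrored on minus
      enhW <- c(enhWidth, rep(0L, cfg@nGenes - nEnh))
      gStart <- gEnd <- eStart <- eEnd <- integer(cfg@nGenes)
      for (i in seq_len(cfg@nGenes)) {
        off <- slotOff[pick[i]] + 500
        if (strandG[i] == "+") {
          eStart[i] <- off + 1
          eEnd[i] <- off + enhW[i]
          gStart[i] <- eEnd[i] + gap[i] + 1
          gEnd[i] <- gStart[i] + geneWidth[i] - 1
        } else {
          gStart[i] <- off + 1
          gEnd[i] <- off + geneWidth[i]
          eStart[i] <- gEnd[i] + gap[i] + 1
          eEnd[i] <- eStart[i] + enhW[i] - 1
        }
      }
      geneId <- sprintf("gene%04d", seq_len(cfg@nGenes))
      genes <- GRanges(slotChr[pick], IRanges(gStart, gEnd),
                       strand = strandG)
      mcols(genes)$gene_id <- geneId
      mcols(genes)$class <- geneClass
      mcols(genes)$tss <- ifelse(strandG == "+", gStart, gEnd)
      mcols(genes)$tts <- ifelse(strandG == "+", gEnd, gStart)
      hasEnh <- which(enhW > 0)
      enhancers <- GRanges(slotChr[pick[hasEnh]],
                           IRanges(eStart[hasEnh], eEnd[hasEnh]))
      mcols(enhancers)$class <- geneClass[hasEnh]
      mcols(enhancers)$hostGene <- geneId[hasEnh]
      ep <- cfg@effectPlan
      mm <- match(geneClass[hasEnh], ep$class)
      mcols(enhancers)$effGenotypeAge1 <- ep$genotypeAge1[mm]
      mcols(enhancers)$effGenotypeAge2 <- ep$genotypeAge2[mm]
      mcols(enhancers)$effAge <- ep$age[mm]
    }
    genomeSeq <- NULL
    if (withSequence) {
      genomeSeq <- DNAStringSet(vapply(names(sl), function(chr) {
        len <- as.integer(sl[[chr]])
        s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        p1 <- seq(17L, len - 8L, by = as.integer(siteEvery))
        p2 <- p1 + 8L
        for (k in seq_along(p1)) {
          s[p1[k]:(p1[k] + 3L)] <- c("G", "A", "T", "C")
          s[p2[k]:(p2[k] + 3L)] <- c("G", "T", "A", "C")
        }
        paste(s, collapse = "")
      }, ""))
    }
    list(genes = genes, enhancers = enhancers, seqlengths = sl,
         genome = genomeSeq, cfg = cfg)
  })
}

binIndexRange <- function(startBp, endBp, binSize) {
  seq((startBp - 1L) %/% binSize + 1L, (endBp - 1L) %/% binSize + 1L)
}

## Expected per-bin mean vectors for each (mark, fraction) in the WT 2-month
## baseline, before genotype/age multipliers.
expectedFractionSignal <- function(truth) {
  cfg <- truth$cfg
  bg <- cfg@backgroundMean; fold <- cfg@enhancerFold
  bins <- lapply(cfg@genome, function(l) ceiling(l / cfg@binSize))
  blank <- lapply(bins, function(n) rep(bg, n))
  names(blank) <- names(cfg@genome)
  markup <- function(vals, gr, classes) {
    if (!length(gr)) return(vals)
    sel <- mcols(gr)$class %in% classes
    g <- gr[sel]
    for (i in seq_along(g)) {
      chr <- as.character(seqnames(g))[i]
      idx <- binIndexRange(start(g)[i], end(g)[i], cfg@binSize)
      idx <- idx[idx <= length(vals[[chr]])]
      vals[[chr]][idx] <- bg * fold
    }
    vals
  }
  act <- c("neuronal", "shared"); gli <- c("glial", "shared")
  list(
    H3K27ac.neun_pos = markup(markup(blank, truth$enhancers, act),
                              truth$genes, act),
    H3K27ac.neun_neg = markup(markup(blank, truth$enhancers, gli),
                              truth$genes, gli),
    H3K27me3.neun_pos = markup(blank, truth$genes, "glial"),
    H3K27me3.neun_neg = markup(blank, truth$genes, "neuronal"))
}

## Apply genotype/age multipliers to a bulk expectation at enhancer bins of
## the affected class only.
applyEffects <- function(vals, truth, genotype, age) {
  cfg <- truth$cfg
  enh <- truth$enhancers
  if (!length(enh)) return(vals)
  eff <- rep(0, length(enh))
  if (age == "6") eff <- eff + mcols(enh)$effAge
  if (genotype == "HD")
    eff <- eff + if (age == "2") mcols(enh)$effGenotypeAge1 else
      mcols(enh)$effGenotypeAge2
  hit <- which(eff != 0)
  for (i in hit) {
    chr <- as.character(seqnames(enh))[i]
    idx <- binIndexRange(start(enh)[i], end(enh)[i], cfg@binSize)
    idx <- idx[idx <= length(vals[[chr]])]
    vals[[chr]][idx] <- vals[[chr]][idx] * 2^eff[i]
  }
  vals
}

#' Simulate ChIP-seq count tracks for all fractions and conditions
#'
#' Generates binned count tracks for sorted NeuN+/NeuN- fractions (H3K27ac
#' and H3K27me3, wild-type) and for bulk H3K27ac across genotype x age, with
#' replicates. Bulk expectation is the mixture-weighted combination of the
#' fraction expectations; genotype and age effects act multiplicatively
#' (2^effect) on the bins of the affected enhancer class only. Counts are
#' negative binomial around the expected means; dispersion 0 yields
#' noise-free tracks equal to the expectation.
#'
#' @param truth output of \code{\link{simulateGenomeAnnotation}}
#' @param replicates replicates per condition (>= 2 for differential tests)
#' @return list with \code{tracks} (named SignalTracks,
#'   mark.fraction.genotype.age.rep), \code{expected} (named lists of
#'   per-chromosome expected mean vectors) and \code{libFactors}
#' @export
simulateChipTracks <- function(truth, replicates = 2L) {
  cfg <- truth$cfg
  withSeed(cfg@seed + 1L, function() {
    frac <- expectedFractionSignal(truth)
    mix <- cfg@mixture
    bulkBase <- mapply(function(p, n) mix * p + (1 - mix) * n,
                       frac$H3K27ac.neun_pos, frac$H3K27ac.neun_neg,
                       SIMPLIFY = FALSE)
    expected <- list()
    for (g in c("WT", "HD")) for (a in c("2", "6"))
      expected[[paste("H3K27ac.bulk", g, a, sep = ".")]] <-
        applyEffects(bulkBase, truth, g, a)
    for (nm in names(frac))
      expected[[paste(nm, "WT", "6", sep = ".")]] <- frac[[nm]]
    tracks <- list(); libFactors <- numeric(0)
    for (nm in names(expected)) {
      for (r in seq_len(replicates)) {
        lib <- runif(1, cfg@libRange[1], cfg@libRange[2])
        vals <- lapply(expected[[nm]], function(mu) {
          m <- mu * lib
          if (cfg@dispersion == 0) m
          else as.numeric(rnbinom(length(m), mu = m,
                                  size = 1 / cfg@dispersion))
        })
        id <- paste0(nm, ".rep", r)
        tracks[[id]] <- SignalTrack(vals, cfg@binSize, cfg@genome)
        libFactors[id] <- lib
      }
    }
    list(tracks = tracks, expected = expected, libFactors = libFactors)
  })
}

#' Simulate RNA-seq counts coupled to the planted enhancer effects
#'
#' Each gene's true log2 fold-change per contrast is \code{r * e + (1 - |r|) *
#' noise} where \code{e} is its attached enhancer's planted effect (0 for
#' enhancer-less genes) and \code{r} is the coupling weight, so coupling 1
#' with zero noise reproduces the enhancer effects exactly and coupling 0
#' decouples transcription from chromatin. Counts are negative binomial over
#' \code{replicates} samples per (genotype, age) condition.
#'
#' @param truth output of \code{\link{simulateGenomeAnnotation}}
#' @param replicates samples per condition
#' @param noiseSd SD of the uncoupled log2FC noise component
#' @param dispersionRna NB dispersion of RNA counts
#' @return list with \code{counts} (genes x samples), \code{samples}
#'   (data.frame genotype/age/replicate), \code{genes}, and true per-gene
#'   log2 effects \code{fcGenotypeAge1}, \code{fcGenotypeAge2}, \code{fcAge}
#' @export
simulateRnaseq <- function(truth, replicates = 4L, noiseSd = 0.3,
                           dispersionRna = 0.05) {
  cfg <- truth$cfg
  withSeed(cfg@seed + 2L, function() {
    genes <- truth$genes
    n <- length(genes)
    enh <- truth$enhancers
    eff1 <- eff2 <- effA <- rep(0, n)
    if (length(enh)) {
      m <- match(mcols(enh)$hostGene, mcols(genes)$gene_id)
      eff1[m] <- mcols(enh)$effGenotypeAge1
      eff2[m] <- mcols(enh)$effGenotypeAge2
      effA[m] <- mcols(enh)$effAge
    }
    r <- cfg@rnaCoupling
    couple <- function(e) r * e + (1 - abs(r)) * rnorm(n, 0, noiseSd)
    fc1 <- couple(eff1); fc2 <- couple(eff2); fcA <- couple(effA)
    base <- pmin(pmax(rlnorm(n, log(200), 1), 20), 5000)
    samples <- expand.grid(replicate = seq_len(replicates),
                           genotype = c("WT", "HD"), age = c("2", "6"),
                           stringsAsFactors = FALSE)
    counts <- matrix(0, n, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      fc <- rep(0, n)
      if (samples$age[j] == "6") fc <- fc + fcA
      if (samples$genotype[j] == "HD")
        fc <- fc + if (samples$age[j] == "2") fc1 else fc2
      lib <- runif(1, cfg@libRange[1], cfg@libRange[2])
      mu <- base * 2^fc * lib
      counts[, j] <- if (dispersionRna == 0) mu else
        as.numeric(rnbinom(n, mu = mu, size = 1 / dispersionRna))
    }
    colnames(counts) <- sprintf("%s_%smo_rep%d", samples$genotype,
                                samples$age, samples$replicate)
    rownames(counts) <- mcols(genes)$gene_id
    list(counts = counts, samples = samples, genes = genes,
         fcGenotypeAge1 = fc1, fcGenotypeAge2 = fc2, fcAge = fcA)
  })
}

#' Simulate a neurons-vs-glia cell-type transcriptome contrast
#'
#' Neuronal-class genes are expressed higher in neurons, glial-class genes
#' higher in glia; unclassed genes are balanced. Returns NB counts for
#' sorted-population samples, from which a cell-type DE table can be computed
#' with \code{\link{deTable}}.
#'
#' @param truth output of \code{\link{simulateGenomeAnnotation}}
#' @param replicates samples per population
#' @param separation log2 expression separation of class genes
#' @param dispersionRna NB dispersion
#' @return list with \code{counts}, \code{group} (factor glia/neuron) and
#'   \code{genes}
#' @export
simulateCelltypeRnaseq <- function(truth, replicates = 4L, separation = 3,
                                   dispersionRna = 0.05) {
  cfg <- truth$cfg
  withSeed(cfg@seed + 3L, function() {
    genes <- truth$genes
    n <- length(genes)
    ctFc <- rep(0, n)
    ctFc[mcols(genes)$class == "neuronal"] <- separation
    ctFc[mcols(genes)$class == "glial"] <- -separation
    ctFc <- ctFc + rnorm(n, 0, 0.2)
    base <- pmin(pmax(rlnorm(n, log(200), 1), 20), 5000)
    group <- factor(rep(c("glia", "neuron"), each = replicates),
                    levels = c("glia", "neuron"))
    counts <- vapply(seq_along(group), function(j) {
      fc <- if (group[j] == "neuron") ctFc / 2 else -ctFc / 2
      as.numeric(rnbinom(n, mu = base * 2^fc, size = 1 / dispersionRna))
    }, numeric(n))
    rownames(counts) <- mcols(genes)$gene_id
    colnames(counts) <- paste0(group, "_rep",
                               rep(seq_len(replicates), 2))
    list(counts = counts, group = group, genes = genes)
  })
}

#' Expected 4C signal from a bead geometry
#'
#' Inverse-power contact model: expected signal of a bead at Euclidean
#' distance d from the bait is \code{A * d^-alpha}.
#'
#' @param coords beads x 3 coordinate matrix
#' @param bait bait bead index
#' @param alpha decay exponent
#' @param A amplitude
#' @return per-bead expected signal (bait bead gets the maximum over the
#'   other beads; it is excluded from scoring downstream)
#' @export
expectedFourcSignal <- function(coords, bait, alpha = 1, A = 1) {
  d <- sqrt(rowSums((coords - matrix(coords[bait, ], nrow(coords), 3,
                                     byrow = TRUE))^2))
  s <- A * d^(-alpha)
  s[bait] <- max(s[-bait])
  s
}

#' Simulate multi-bait 4C fragment profiles from a bead geometry
#'
#' Fragment-level expected signal decays with bait-bead distance as
#' \code{A * d^-alpha}; counts receive multiplicative log-normal noise and
#' are integerized. At least 4 baits are required (multi-viewpoint
#' modelling).
#'
#' @param coords beads x 3 true coordinate matrix
#' @param baits bead indices of the baits (>= 4)
#' @param fragPerBead restriction fragments per bead
#' @param alpha decay exponent
#' @param noiseSd log-normal sigma (0 = noise-free, counts not integerized)
#' @param meanCount target mean fragment count (sets the amplitude A)
#' @param seed RNG seed
#' @param chrom chromosome name of the synthetic locus
#' @param fragBp fragment width in bp
#' @return named list of \linkS4class{FourCProfile}, one per bait
#' @export
simulateFourC <- function(coords, baits, fragPerBead = 25L, alpha = 1,
                          noiseSd = 0.2, meanCount = 50, seed = 1L,
                          chrom = "chrLocus", fragBp = 250L) {
  coords <- as.matrix(coords)
  nBeads <- nrow(coords)
  if (length(baits) < 4L) stop("at least 4 baits are required")
  if (any(baits < 1L | baits > nBeads)) stop("bait index out of range")
  withSeed(seed, function() {
    nFrag <- nBeads * fragPerBead
    frags <- GRanges(chrom, IRanges((seq_len(nFrag) - 1L) * fragBp + 1L,
                                    seq_len(nFrag) * fragBp))
    sig <- lapply(baits, function(b)
      expectedFourcSignal(coords, b, alpha = alpha))
    ## one global amplitude across baits: the transform back to distances
    ## assumes a shared contact-to-signal scale
    A <- meanCount / median(unlist(sig))
    out <- list()
    for (i in seq_along(baits)) {
      b <- baits[i]
      s <- sig[[i]]
      muFrag <- rep(A * s, each = fragPerBead)
      cnt <- if (noiseSd == 0) muFrag else
        round(muFrag * rlnorm(nFrag, 0, noiseSd))
      baitIdx <- (b - 1L) * fragPerBead + (fragPerBead + 1L) %/% 2L
      out[[paste0("bead", b)]] <- FourCProfile(
        frags, cnt, baitIdx,
        sampleInfo = list(baitBead = b, alpha = alpha))
    }
    out
  })
}

#' Planted two-TAD bead geometry
#'
#' Beads form two compact blobs (TADs) whose centres are separated by much
#' more than the blob radius; \code{boundary} is the first bead of the second
#' TAD. The resulting distance matrix has the two-block structure whose
#' insulation minimum marks the TAD border.
#'
#' @param nBeads total beads
#' @param boundary first bead index of the second TAD
#' @param radius within-TAD blob radius (model units)
#' @param separation centre-to-centre distance of the two TADs
#' @param seed RNG seed
#' @return list with \code{coords} (beads x 3) and \code{boundary}
#' @export
plantedTadGeometry <- function(nBeads = 40L, boundary = 21L, radius = 1,
                               separation = 8, seed = 1L) {
  withSeed(seed, function() {
    sphere <- function(n, centre, r) {
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2)) * r * runif(n)^(1 / 3)
      sweep(u, 2, centre, "+")
    }
    coords <- rbind(
      sphere(boundary - 1L, c(0, 0, 0), radius),
      sphere(nBeads - boundary + 1L, c(separation, 0, 0), radius))
    list(coords = coords, boundary = as.integer(boundary))
  })
}
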