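#' Average replicate tracks
#'
#' Bin-wise mean of a list of \linkS4class{SignalTrack}s on the same genome
#' and bin size.
#'
#' @param tracks list of SignalTracks
#' @return a \linkS4class{SignalTrack}
#' @export
averageTracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  vals <- lapply(names(trackValues(ref)), function(chr) {
    rowMeans(vapply(tracks, function(t) trackValues(t)[[chr]],
                    numeric(length(trackValues(ref)[[chr]]))))
  })
  names(vals) <- names(trackValues(ref))
  SignalTrack(vals, binSize(ref), ref@seqlengths,
              normalization = normalizationState(ref))
}

#' Seeded background regions disjoint from a region set
#'
#' Samples fixed-width regions uniformly over the genome, rejecting any that
#' overlap \code{exclude}; used to estimate background-equalizing size
#' factors.
#'
#' @param seqlengths named chromosome lengths
#' @param exclude GRanges to avoid
#' @param n number of regions
#' @param width region width in bp
#' @param seed RNG seed
#' @return GRanges of background regions
#' @export
sampleBackgroundRegions <- function(seqlengths, exclude, n = 300L,
                                    width = 2000L, seed = 1L) {
  withSeed(seed, function() {
    out <- GRanges()
    tries <- 0L
    while (length(out) < n && tries < 50L * n) {
      tries <- tries + 1L
      chr <- sample(names(seqlengths), 1L,
                    prob = as.numeric(seqlengths) / sum(seqlengths))
      s <- sample.int(seqlengths[[chr]] - width, 1L)
      cand <- GRanges(chr, IRanges(s, s + width - 1L))
      if (!overlapsAny(cand, exclude, ignore.strand = TRUE) &&
          !overlapsAny(cand, out, ignore.strand = TRUE))
        out <- suppressWarnings(c(out, cand))
    }
    if (length(out) < n) stop("could not place enough background regions")
    out
  })
}

#' Run the integrative accelerated-aging analysis on a simulated study
#'
#' Executes the full desk-scale pipeline on synthetic data with planted
#' ground truth: island calling on every bulk and sorted-fraction H3K27ac
#' track, high-confidence region universes, background-equalized size
#' factors, exact conditional differential tests for the genotype (HD vs WT
#' at the early age) and age (6 vs 2 months in WT) contrasts, the NeuN+/-
#' enhancer catalogue, cell-type attribution of differential regions,
#' age-by-genotype concordance, RNA differential expression, gene-profile
#' k-means clustering and the cluster/cell-type enrichment tests.
#'
#' @param cfg a \linkS4class{SimulationConfig}
#' @param genoCutoff adjusted-p cutoff for genotype differential regions
#' @param topN top dysregulated genes used in the enrichment tests (scaled
#'   to the synthetic gene universe)
#' @param k k-means cluster count
#' @return list with the truth, region universes, differential tables,
#'   catalogue, attribution counts, concordance, RNA DE table, cluster
#'   assignment and enrichment results
#' @export
runStudyPipeline <- function(cfg = simulationConfig(), genoCutoff = 1e-5,
                             topN = 100L, k = 7L) {
  truth <- simulateGenomeAnnotation(cfg)
  chip <- simulateChipTracks(truth)
  tracks <- chip$tracks
  seed0 <- cfg@seed

  ## island universes
  bulkId <- function(g, a) paste0("H3K27ac.bulk.", g, ".", a, ".rep", 1:2)
  callSet <- function(ids, off) lapply(seq_along(ids), function(i)
    callIslands(tracks[[ids[i]]], islandParams(), seed = seed0 + off + i))
  hc <- list()
  off <- 100L
  for (g in c("WT", "HD")) for (a in c("2", "6")) {
    hc[[paste(g, a)]] <- highConfidenceIslands(callSet(bulkId(g, a), off))
    off <- off + 10L
  }
  universe <- reduce(do.call(c, unname(hc)), ignore.strand = TRUE)

  sortedIds <- function(fr) paste0("H3K27ac.", fr, ".WT.6.rep", 1:2)
  hcPos <- highConfidenceIslands(callSet(sortedIds("neun_pos"), 200L))
  hcNeg <- highConfidenceIslands(callSet(sortedIds("neun_neg"), 220L))
  catUniverse <- reduce(c(hcPos, hcNeg), ignore.strand = TRUE)

  ## counts and size factors
  bulkIds <- as.vector(vapply(c("WT", "HD"), function(g)
    vapply(c("2", "6"), function(a) bulkId(g, a), character(2)),
    character(4)))
  bulkMeta <- do.call(rbind, lapply(strsplit(bulkIds, ".", fixed = TRUE),
    function(p) data.frame(genotype = p[3], age = p[4], rep = p[5])))
  bulkMeta$group <- paste(bulkMeta$genotype, bulkMeta$age, sep = ".")
  bg <- sampleBackgroundRegions(cfg@genome,
                                c(universe, catUniverse,
                                  granges(truth$enhancers),
                                  granges(truth$genes)),
                                seed = seed0 + 300L)
  bulkTracks <- tracks[bulkIds]
  bgCounts <- regionCounts(bulkTracks, bg)
  sf <- computeSizeFactors(bgCounts)
  counts <- regionCounts(bulkTracks, universe, sampleData = bulkMeta)
  colData(counts)$sizeFactor <- sf

  ## differential contrasts (exact conditional mode, stringent thresholds)
  diffGeno <- differentialTest(counts, c("WT.2", "HD.2"), dispersion = 0)
  diffAge <- differentialTest(counts, c("WT.2", "WT.6"), dispersion = 0)

  ## cell-type enhancer catalogue
  posIds <- sortedIds("neun_pos"); negIds <- sortedIds("neun_neg")
  sortedBg <- regionCounts(tracks[c(posIds, negIds)], bg)
  sfSorted <- computeSizeFactors(sortedBg)
  catPos <- regionCounts(tracks[posIds], catUniverse)
  colData(catPos)$sizeFactor <- sfSorted[posIds]
  catNeg <- regionCounts(tracks[negIds], catUniverse)
  colData(catNeg)$sizeFactor <- sfSorted[negIds]
  catalogue <- buildEnhancerCatalogue(catPos, catNeg)

  ## attribution of significant genotype regions
  sig <- which(diffGeno$adj_p < genoCutoff)
  sigRegions <- universe[sig]
  mcols(sigRegions)$direction <- diffGeno$direction[sig]
  mcols(sigRegions)$log2FC <- diffGeno$log2FC[sig]
  attribution <- attributeRegions(sigRegions, catalogue)

  ## age-by-genotype concordance
  concordance <- concordanceAnalysis(universe, diffGeno, diffAge, catalogue)

  ## RNA differential expression and gene-profile clustering
  rna <- simulateRnaseq(truth)
  sel2 <- rna$samples$age == "2"
  de <- deTable(rna$counts[, sel2], rna$samples$genotype[sel2],
                c("WT", "HD"), genes = truth$genes)
  sortedAvg <- list(
    H3K27ac.neun_pos = normalizeTrack1x(averageTracks(tracks[posIds])),
    H3K27ac.neun_neg = normalizeTrack1x(averageTracks(tracks[negIds])),
    H3K27me3.neun_pos = normalizeTrack1x(averageTracks(
      tracks[paste0("H3K27me3.neun_pos.WT.6.rep", 1:2)])),
    H3K27me3.neun_neg = normalizeTrack1x(averageTracks(
      tracks[paste0("H3K27me3.neun_neg.WT.6.rep", 1:2)])))
  profiles <- geneProfileMatrix(sortedAvg, truth$genes)
  assignment <- clusterGeneProfiles(profiles, k = k, seed = seed0 + 400L)
  ## neuronal-archetype cluster: centroid most enriched in NeuN+ H3K27ac
  ## over NeuN- H3K27ac (concatenation order of `profiles`)
  nbv <- ncol(profiles[[1]])
  sigCentroid <- rowMeans(assignment$centers[, seq_len(nbv)]) -
    rowMeans(assignment$centers[, nbv + seq_len(nbv)])
  neuronalCluster <- which.max(sigCentroid)
  enrDown <- clusterEnrichment(de, assignment, topN = topN,
                               rankKey = "adj_p", direction = "down")
  enrUp <- clusterEnrichment(de, assignment, topN = topN,
                             rankKey = "adj_p", direction = "up")

  ## cell-type specificity of top dysregulated genes
  ct <- simulateCelltypeRnaseq(truth)
  ctDe <- deTable(ct$counts, ct$group, c("glia", "neuron"),
                  genes = truth$genes)
  topDown <- rankTopGenes(de[de$gene_id %in% ctDe$gene_id, ], topN,
                          "adj_p", "down")
  topUp <- rankTopGenes(de[de$gene_id %in% ctDe$gene_id, ], topN,
                        "adj_p", "up")
  specDown <- celltypeSpecificityEnrichment(topDown, ctDe)
  specUp <- celltypeSpecificityEnrichment(topUp, ctDe)

  list(truth = truth, universe = universe, catUniverse = catUniverse,
       counts = counts, diffGenotype = diffGeno, diffAge = diffAge,
       catalogue = catalogue, attribution = attribution,
       concordance = concordance, de = de, celltypeDe = ctDe,
       assignment = assignment, neuronalCluster = neuronalCluster,
       enrichmentDown = enrDown, enrichmentUp = enrUp,
       specificityDown = specDown, specificityUp = specUp)
}
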