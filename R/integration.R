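#' Attribute differential regions to cell types
#'
#' A region overlapping (>= \code{minOverlapBp}) only neuronal catalogue
#' entries is labelled Neuronal, only glial entries Glial; regions touching
#' neither, or both (the ambiguity rule), are Non-specific. Every input
#' region receives exactly one label.
#'
#' @param regions GRanges of differential regions (metadata such as log2FC,
#'   direction is kept)
#' @param catalogue an \linkS4class{EnhancerCatalogue}
#' @param minOverlapBp minimum overlap (default 1 bp)
#' @return list with \code{regions} (input GRanges plus a
#'   \code{celltype_label} column) and \code{counts} (direction x label
#'   table when a \code{direction} column is present, else label counts)
#' @export
attributeRegions <- function(regions, catalogue, minOverlapBp = 1L) {
  cat <- catalogueRegions(catalogue)
  neu <- overlapsAny(regions, cat[mcols(cat)$label == "neuronal"],
                     minoverlap = minOverlapBp, ignore.strand = TRUE)
  gli <- overlapsAny(regions, cat[mcols(cat)$label == "glial"],
                     minoverlap = minOverlapBp, ignore.strand = TRUE)
  lab <- ifelse(neu & !gli, "Neuronal",
                ifelse(gli & !neu, "Glial", "Non-specific"))
  mcols(regions)$celltype_label <- lab
  counts <- if (!is.null(mcols(regions)$direction))
    table(direction = mcols(regions)$direction, label = lab)
  else table(label = lab)
  list(regions = regions, counts = counts)
}

#' Signal metaprofile over regions or genes
#'
#' Resamples 1x-normalized coverage onto a fixed bin scheme per feature and
#' averages across features. Two schemes: \code{"region"} uses a fixed-width
#' window centred on each region midpoint; \code{"gene"} uses fixed-width
#' flanks plus a length-scaled gene body (TSS to TTS), strand-flipped so bin
#' 1 is always the 5' end. Features extending past chromosome ends are
#' clipped with a warning.
#'
#' @param track a \linkS4class{SignalTrack} normalized to 1x coverage
#' @param features GRanges (regions, or genes with strand)
#' @param scheme \code{"gene"} or \code{"region"}
#' @param flankBp flank size in bp (gene scheme)
#' @param flankBins bins per flank (gene scheme)
#' @param bodyBins length-scaled gene-body bins (gene scheme)
#' @param windowBp total window width (region scheme)
#' @param windowBins bins across the window (region scheme)
#' @return list with \code{profile} (mean profile across features),
#'   \code{matrix} (features x bins) and \code{featureMeans} (per-feature
#'   mean density, for boxplots)
#' @export
metaprofile <- function(track, features, scheme = c("gene", "region"),
                        flankBp = 2000, flankBins = 20, bodyBins = 100,
                        windowBp = 4000, windowBins = 100) {
  scheme <- match.arg(scheme)
  if (normalizationState(track) != "rpgc_1x")
    stop("track must be normalized to 1x genome coverage")
  bs <- binSize(track)
  nf <- length(features)
  nb <- if (scheme == "gene") 2 * flankBins + bodyBins else windowBins
  mat <- matrix(NA_real_, nf, nb)
  clipped <- FALSE
  css <- lapply(trackValues(track), function(v) c(0, cumsum(v)))
  for (i in seq_len(nf)) {
    chr <- as.character(seqnames(features))[i]
    v <- trackValues(track)[[chr]]
    if (is.null(v)) next
    chrLen <- track@seqlengths[[chr]]
    if (scheme == "gene") {
      s <- start(features)[i] - 1; e <- end(features)[i]
      breaks <- c(seq(s - flankBp, s, length.out = flankBins + 1),
                  seq(s, e, length.out = bodyBins + 1)[-1],
                  seq(e, e + flankBp, length.out = flankBins + 1)[-1])
    } else {
      mid <- floor((start(features)[i] - 1 + end(features)[i]) / 2)
      breaks <- seq(mid - windowBp / 2, mid + windowBp / 2,
                    length.out = windowBins + 1)
    }
    if (breaks[1] < 0 || breaks[length(breaks)] > chrLen) {
      clipped <- TRUE
      breaks <- pmin(pmax(breaks, 0), chrLen)
    }
    prof <- segmentMeans(v, bs, breaks, cs = css[[chr]])
    if (as.character(strand(features))[i] == "-") prof <- rev(prof)
    mat[i, ] <- prof
  }
  if (clipped) warning("feature(s) extending past chromosome bounds clipped")
  list(profile = colMeans(mat, na.rm = TRUE), matrix = mat,
       featureMeans = rowMeans(mat, na.rm = TRUE))
}

#' Gene profile matrices for a set of tracks
#'
#' Builds the genes x bins matrix (gene scheme of \code{\link{metaprofile}})
#' for each supplied track, typically H3K27ac and H3K27me3 in NeuN+ and
#' NeuN- fractions.
#'
#' @param tracks named list of 1x-normalized \linkS4class{SignalTrack}s
#' @param genes GRanges with a \code{gene_id} metadata column
#' @param ... bin-scheme arguments passed to \code{\link{metaprofile}}
#' @return named list of genes x bins matrices (rownames = gene ids)
#' @export
geneProfileMatrix <- function(tracks, genes, ...) {
  lapply(tracks, function(tr) {
    m <- metaprofile(tr, genes, scheme = "gene", ...)$matrix
    rownames(m) <- mcols(genes)$gene_id
    m
  })
}

## Seeded k-means++ initial centres.
kmeansPlusPlus <- function(x, k) {
  n <- nrow(x)
  centres <- matrix(NA_real_, k, ncol(x))
  centres[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centres[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- if (sum(d2) == 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2)
    centres[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centres[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centres
}

#' Cluster gene epigenetic profiles by k-means
#'
#' Concatenates the per-(mark, fraction) profile matrices per gene and runs
#' k-means with seeded k-means++ initialization, keeping the best of
#' \code{restarts} runs by total within-cluster sum of squares.
#' Deterministic under a fixed seed.
#'
#' @param profiles named list of genes x bins matrices (identical rownames),
#'   or a single matrix
#' @param k number of clusters (default 7)
#' @param seed RNG seed
#' @param restarts number of k-means++ restarts
#' @param concatenate concatenate matrices column-wise (default); if FALSE,
#'   only the first matrix is used
#' @return list with \code{cluster} (named integer vector), \code{centers},
#'   \code{totWithinss} and \code{k}
#' @export
clusterGeneProfiles <- function(profiles, k = 7L, seed = 1L, restarts = 5L,
                                concatenate = TRUE) {
  if (is.matrix(profiles)) profiles <- list(profiles)
  ids <- rownames(profiles[[1]])
  x <- if (concatenate) do.call(cbind, profiles) else profiles[[1]]
  x <- x[, colSums(is.na(x)) == 0, drop = FALSE]
  keep <- rowSums(!is.finite(x)) == 0
  x <- x[keep, , drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of genes")
  best <- NULL
  withSeed(seed, function() {
    for (r in seq_len(restarts)) {
      init <- kmeansPlusPlus(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss)
        best <<- km
    }
  })
  list(cluster = setNames(as.integer(best$cluster), ids[keep]),
       centers = best$centers, totWithinss = best$tot.withinss,
       k = as.integer(k))
}

rankTopGenes <- function(de, topN, rankKey = c("raw_p", "adj_p"),
                         direction = c("down", "up")) {
  rankKey <- match.arg(rankKey)
  direction <- match.arg(direction)
  sub <- de[if (direction == "down") de$log2FC < 0 else de$log2FC > 0, ,
            drop = FALSE]
  if (topN > nrow(sub))
    stop("top_n exceeds the ranked list length (", nrow(sub), ")")
  sub <- sub[order(sub[[rankKey]], sub$gene_id), , drop = FALSE]
  sub$gene_id[seq_len(topN)]
}

#' Cluster enrichment of top dysregulated genes
#'
#' The top-N genes of one direction (ranked by raw or adjusted p, ties
#' broken by gene id) are compared to each cluster's expected share of the
#' clustered universe with a two-sided exact binomial test; Bonferroni
#' family size is the number of clusters.
#'
#' @param de DE table (gene_id, log2FC, raw_p, adj_p)
#' @param assignment output of \code{\link{clusterGeneProfiles}}
#' @param topN number of top genes (default 300)
#' @param rankKey \code{"raw_p"} or \code{"adj_p"}
#' @param direction \code{"down"} or \code{"up"}
#' @return data.frame per cluster: observed, expected, proportion, raw_p,
#'   adj_p (Bonferroni)
#' @export
clusterEnrichment <- function(de, assignment, topN = 300L,
                              rankKey = c("raw_p", "adj_p"),
                              direction = c("down", "up")) {
  cl <- assignment$cluster
  de <- de[de$gene_id %in% names(cl), , drop = FALSE]
  if (!nrow(de)) stop("clustered and DE gene universes do not intersect")
  top <- rankTopGenes(de, topN, rankKey, direction)
  k <- assignment$k
  sizes <- tabulate(cl, nbins = k)
  topCl <- cl[top]
  obs <- tabulate(topCl, nbins = k)
  expProp <- sizes / length(cl)
  pv <- vapply(seq_len(k), function(j) {
    if (expProp[j] <= 0 || expProp[j] >= 1) return(1)
    binomialEnrichment(obs[j], length(top), expProp[j])
  }, 0)
  data.frame(cluster = seq_len(k), clusterSize = sizes,
             observed = obs, expected = length(top) * expProp,
             raw_p = pv, adj_p = adjustPvalues(pv, "bonferroni", m = k))
}

#' Cell-type specificity enrichment of a gene set
#'
#' Specific genes in the neurons-vs-glia table are those with adjusted p
#' below \code{adjPCutoff}; positive log2FC means neuronal-specific,
#' negative glial-specific. The null proportion is the neuronal share among
#' all specific genes; the test is two-sided exact binomial on the neuronal
#' count among the query genes that are specific.
#'
#' @param topGenes character vector of gene ids
#' @param celltypeDe DE table for the neurons-vs-glia contrast
#' @param adjPCutoff specificity cutoff (default 0.05)
#' @return list with counts (neuronal, glial), null proportion and p
#' @export
celltypeSpecificityEnrichment <- function(topGenes, celltypeDe,
                                          adjPCutoff = 0.05) {
  spec <- celltypeDe[celltypeDe$adj_p < adjPCutoff & celltypeDe$log2FC != 0, ,
                     drop = FALSE]
  if (!nrow(spec)) stop("no cell-type-specific genes in the table")
  p0 <- mean(spec$log2FC > 0)
  inSet <- spec[spec$gene_id %in% topGenes, , drop = FALSE]
  nNeu <- sum(inSet$log2FC > 0); nGli <- sum(inSet$log2FC < 0)
  tot <- nNeu + nGli
  pv <- if (tot == 0 || p0 <= 0 || p0 >= 1) NA_real_ else
    binomialEnrichment(nNeu, tot, p0)
  list(neuronal = nNeu, glial = nGli, nullProportion = p0, p = pv)
}

#' Linear regression of transcriptional on chromatin-mark changes
#'
#' Ordinary least squares of mRNA log2FC on H3K27ac log2FC per stratum; the
#' strata (all, up, down, non-significant) are defined by the RNA table's
#' adjusted p and fold-change direction.
#'
#' @param chipFc named per-gene chromatin log2FC
#' @param de DE table with gene_id, log2FC, adj_p
#' @param adjPCutoff significance cutoff for up/down strata
#' @return data.frame per stratum: n, slope, intercept, r (Pearson), p (of
#'   the fitted model)
#' @export
chipRnaRegression <- function(chipFc, de, adjPCutoff = 0.05) {
  common <- intersect(names(chipFc), de$gene_id)
  de <- de[match(common, de$gene_id), , drop = FALSE]
  x <- chipFc[common]; y <- de$log2FC
  sig <- de$adj_p < adjPCutoff
  strata <- list(all = rep(TRUE, length(x)),
                 down = sig & y < 0, up = sig & y > 0, ns = !sig)
  out <- lapply(names(strata), function(s) {
    sel <- strata[[s]]
    if (sum(sel) < 3)
      return(data.frame(stratum = s, n = sum(sel), slope = NA, intercept = NA,
                        r = NA, p = NA))
    xs <- x[sel]; ys <- y[sel]
    if (sd(xs) == 0) stop("constant predictor in stratum ", s)
    fit <- lm(ys ~ xs)
    ct <- cor.test(xs, ys)
    data.frame(stratum = s, n = sum(sel), slope = coef(fit)[2],
               intercept = coef(fit)[1], r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Age-by-genotype concordance of differential regions
#'
#' Regions passing the raw-p filter in both the genotype and the age
#' contrast are retained and attributed to cell types via the catalogue.
#' Reports per-label mean log2FCs and sign-concordance fractions, Spearman's
#' rho between the two contrasts' log2FCs, and a per-region z-score matrix
#' of normalized signal with an average-linkage (Euclidean) hierarchical
#' ordering.
#'
#' @param regions GRanges of the common region universe
#' @param genotypeDiff,ageDiff differential tables over \code{regions} (rows
#'   aligned), with log2FC and raw_p
#' @param catalogue an \linkS4class{EnhancerCatalogue}
#' @param signal optional regions x conditions matrix of normalized means
#'   for the z-score heatmap
#' @param pCutoff raw-p filter (default 0.05)
#' @return list with \code{table} (per-region log2FCs and labels),
#'   \code{byLabel} (mean FCs and concordance per label),
#'   \code{concordance} (overall), \code{spearman} (estimate and p),
#'   \code{zscore} and \code{order}
#' @export
concordanceAnalysis <- function(regions, genotypeDiff, ageDiff, catalogue,
                                signal = NULL, pCutoff = 0.05) {
  stopifnot(length(regions) == nrow(genotypeDiff),
            length(regions) == nrow(ageDiff))
  keep <- genotypeDiff$raw_p < pCutoff & ageDiff$raw_p < pCutoff
  if (!any(keep))
    stop(sprintf(paste0("no region passes p<%g in both contrasts ",
                        "(genotype: %d, age: %d, both: 0)"),
                 pCutoff, sum(genotypeDiff$raw_p < pCutoff),
                 sum(ageDiff$raw_p < pCutoff)))
  sel <- regions[keep]
  att <- attributeRegions(sel, catalogue)
  lab <- mcols(att$regions)$celltype_label
  tab <- data.frame(
    chrom = as.character(seqnames(sel)), start = start(sel) - 1L,
    end = end(sel), label = lab,
    log2FC_genotype = genotypeDiff$log2FC[keep],
    log2FC_age = ageDiff$log2FC[keep])
  conc <- sign(tab$log2FC_genotype) == sign(tab$log2FC_age)
  byLabel <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$label),
    function(ix) data.frame(
      n = length(ix),
      meanFcGenotype = mean(tab$log2FC_genotype[ix]),
      meanFcAge = mean(tab$log2FC_age[ix]),
      concordance = mean(conc[ix]))))
  ct <- suppressWarnings(
    cor.test(tab$log2FC_genotype, tab$log2FC_age, method = "spearman"))
  z <- ord <- NULL
  if (!is.null(signal)) {
    z <- zscoreMatrix(signal[keep, , drop = FALSE])
    ord <- hclust(dist(z), method = "average")$order
  }
  list(table = tab, byLabel = byLabel, concordance = mean(conc),
       spearman = list(rho = unname(ct$estimate), p = ct$p.value),
       zscore = z, order = ord)
}

#' Chromosome enrichment of differentially expressed genes
#'
#' Per chromosome: observed DEG count vs the chromosome's expected share of
#' the annotated universe, two-sided exact binomial, Bonferroni across
#' chromosomes; also reports the percentage of DEGs per chromosome.
#'
#' @param de DE table with gene_id, adj_p and chromosome
#' @param universe GRanges of all annotated genes (gene_id metadata)
#' @param adjPCutoff DEG definition (default 0.05)
#' @return data.frame per chromosome: genes, degs, pctDeg, expected, raw_p,
#'   adj_p
#' @export
chromosomeEnrichment <- function(de, universe, adjPCutoff = 0.05) {
  uniChrom <- as.character(seqnames(universe))
  chroms <- unique(uniChrom)
  degs <- de[!is.na(de$adj_p) & de$adj_p < adjPCutoff, , drop = FALSE]
  if (length(bad <- setdiff(unique(degs$chromosome), chroms)))
    stop("DE chromosome absent from the universe: ",
         paste(bad, collapse = ", "))
  nUni <- table(factor(uniChrom, levels = chroms))
  nDeg <- table(factor(degs$chromosome, levels = chroms))
  total <- nrow(degs)
  pv <- vapply(chroms, function(ch) {
    p0 <- nUni[[ch]] / length(universe)
    if (total == 0 || p0 <= 0 || p0 >= 1) return(1)
    binomialEnrichment(nDeg[[ch]], total, p0)
  }, 0)
  data.frame(chromosome = chroms, genes = as.integer(nUni),
             degs = as.integer(nDeg),
             pctDeg = if (total > 0) 100 * as.integer(nDeg) / total else 0,
             expected = total * as.integer(nUni) / length(universe),
             raw_p = pv,
             adj_p = adjustPvalues(pv, "bonferroni", m = length(chroms)))
}

#' Group-wise z-score comparison of a gene set
#'
#' Gene-wise z-scores (across all samples) for the gene set are pooled per
#' sample group; groups are compared with the Kruskal-Wallis rank test (tie
#' corrected) and pairwise Wilcoxon follow-ups BH-adjusted.
#'
#' @param expr genes x samples expression matrix
#' @param geneSet rownames subset to analyse
#' @param groups factor of sample groups (>= 2 groups, >= 2 samples each)
#' @return list with \code{distributions} (list of per-group pooled
#'   z-scores), \code{H}, \code{p} and \code{pairwise} (BH-adjusted matrix)
#' @export
groupwiseZscoreTest <- function(expr, geneSet, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 observations")
  expr <- as.matrix(expr)
  z <- suppressWarnings(zscoreMatrix(expr[rownames(expr) %in% geneSet, ,
                                          drop = FALSE]))
  vals <- as.vector(z)
  grp <- factor(rep(groups, each = nrow(z)), levels = levels(groups))
  kw <- kruskal.test(vals, grp)
  pw <- suppressWarnings(
    pairwise.wilcox.test(vals, grp, p.adjust.method = "BH"))
  list(distributions = split(vals, grp),
       H = unname(kw$statistic), p = kw$p.value, pairwise = pw$p.value)
}

#' Nuclear fraction percentages from sorting event counts
#'
#' NeuN+ % = NeuN+ / (NeuN+ + NeuN-) x 100, and the complement for NeuN-.
#' A warning is emitted below 30,000 total singlet-gated events.
#'
#' @param neunPos,neunNeg event counts
#' @return named numeric: neunPosPct, neunNegPct (summing to 100)
#' @export
nuclearFractions <- function(neunPos, neunNeg) {
  tot <- neunPos + neunNeg
  if (tot <= 0) stop("total events must be > 0")
  if (tot < 30000)
    warning("fewer than 30,000 singlet gated events (", tot, ")")
  c(neunPosPct = 100 * neunPos / tot, neunNegPct = 100 * neunNeg / tot)
}
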