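#' Background-equalizing size factors
#'
#' Median-of-ratios over background regions: each sample's factor is the
#' median across background regions of its count divided by the region's
#' geometric mean across samples (regions with a zero count in any sample are
#' dropped from the median, as usual for this estimator). Factors are
#' normalized to geometric mean 1; scaling one sample's counts by c scales
#' its factor by c.
#'
#' @param counts background-region x sample count matrix (or a
#'   \linkS4class{RegionCounts} over background regions)
#' @return positive per-sample size factors
#' @export
computeSizeFactors <- function(counts) {
  if (is(counts, "RegionCounts"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0))
    stop("sample with all-zero background counts")
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) stop("no background region with nonzero counts in all samples")
  gm <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  f <- apply(counts[ok, , drop = FALSE] / gm, 2L, median)
  f / exp(mean(log(f)))
}

## Core NB differential test on a count matrix.
##  dispersion = "moments": per-region method-of-moments estimates shrunk
##    toward a parametric trend (a0 + a1/mu), moderated t reference.
##  dispersion = numeric > 0: fixed dispersion, moderated t.
##  dispersion = 0 or "exact": exact conditional Poisson (binomial) test.
nbCore <- function(counts, sizeFactors, group, dispersion = "moments",
                   priorDf = 40, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  group <- factor(group)
  lv <- levels(group)
  if (length(lv) != 2L) stop("contrast requires exactly 2 groups")
  g1 <- which(group == lv[1]); g2 <- which(group == lv[2])
  if (!length(g1) || !length(g2)) stop("a contrast group has no samples")
  q <- sweep(counts, 2L, sizeFactors, "/")
  n1 <- length(g1); n2 <- length(g2)
  mu1 <- rowMeans(q[, g1, drop = FALSE])
  mu2 <- rowMeans(q[, g2, drop = FALSE])
  log2FC <- log2((mu2 + pseudocount) / (mu1 + pseudocount))

  exact <- identical(dispersion, "exact") ||
    (is.numeric(dispersion) && dispersion == 0)
  if (exact) {
    k1 <- rowSums(counts[, g1, drop = FALSE])
    k2 <- rowSums(counts[, g2, drop = FALSE])
    p0 <- sum(sizeFactors[g2]) / sum(sizeFactors[c(g1, g2)])
    pv <- vapply(seq_along(k1), function(i) {
      tot <- k1[i] + k2[i]
      if (tot == 0) return(1)
      binomialEnrichment(round(k2[i]), round(tot), p0)
    }, 0)
    df <- Inf
  } else {
    if (is.numeric(dispersion)) {
      alpha <- rep(dispersion, nrow(counts))
      df <- Inf
    } else {
      if (n1 < 2L || n2 < 2L)
        stop(">=2 samples per group required for dispersion estimation")
      v1 <- apply(q[, g1, drop = FALSE], 1L, var)
      v2 <- apply(q[, g2, drop = FALSE], 1L, var)
      vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      mubar <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
      aHat <- pmax(0, (vw - mubar) / pmax(mubar, 1e-8)^2)
      ## parametric trend alpha(mu) = a0 + a1/mu fitted on moderately
      ## expressed regions, clamped to be non-negative
      use <- mubar > 1
      aTrend <- if (sum(use) >= 10) {
        fit <- tryCatch(lm(aHat[use] ~ I(1 / mubar[use])),
                        error = function(e) NULL)
        if (is.null(fit)) rep(median(aHat[use]), nrow(counts))
        else pmax(0, coef(fit)[1] + coef(fit)[2] / pmax(mubar, 1e-8))
      } else rep(median(aHat), nrow(counts))
      resDf <- n1 + n2 - 2
      alpha <- (resDf * aHat + priorDf * aTrend) / (resDf + priorDf)
      df <- Inf
    }
    vlog <- function(mu, n) (1 / (mu + pseudocount) + alpha) / n
    se <- sqrt(vlog(mu1, n1) + vlog(mu2, n2))
    z <- (log(mu2 + pseudocount) - log(mu1 + pseudocount)) / se
    pv <- 2 * pt(-abs(z), df = df)
    pv <- pmin(1, pv)
  }
  data.frame(
    baseMean1 = mu1, baseMean2 = mu2, log2FC = log2FC,
    raw_p = pv, adj_p = adjustPvalues(pv, "BH"),
    direction = ifelse(log2FC > 0, "up", ifelse(log2FC < 0, "down", "up")),
    stringsAsFactors = FALSE)
}

#' Negative-binomial differential enrichment test
#'
#' Per region: group means of size-factor-normalized counts, log2 fold-change
#' with a 0.5 pseudocount, a Wald test with method-of-moments dispersion
#' strongly shrunk toward a parametric trend (prior weight \code{priorDf}
#' residual-df equivalents), and BH adjustment across regions. With
#' \code{dispersion = 0} (or \code{"exact"}) the test degenerates to the
#' exact conditional Poisson test: given the two groups' summed raw counts,
#' the second group's total is binomial with proportion given by the size
#' factors, tested two-sided. The Wald variance is computed on normalized
#' counts, so rescaling a sample's counts together with its size factor
#' leaves all p-values unchanged.
#'
#' @param rc a \linkS4class{RegionCounts}
#' @param contrast length-2 character: (group1, group2); log2FC is group2
#'   over group1
#' @param groupCol name of the \code{colData} column holding the groups
#' @param dispersion \code{"moments"} (default), a fixed numeric dispersion,
#'   or 0/\code{"exact"} for the exact conditional test
#' @param priorDf prior degrees of freedom of the dispersion trend
#' @return data.frame of \code{DifferentialRegion} rows: baseMean1/2,
#'   log2FC, raw_p, adj_p, direction (one row per region, region order kept)
#' @export
differentialTest <- function(rc, contrast, groupCol = "group",
                             dispersion = "moments", priorDf = 40) {
  cd <- colData(rc)
  if (!groupCol %in% colnames(cd)) stop("missing colData column: ", groupCol)
  gv <- as.character(cd[[groupCol]])
  if (!all(contrast %in% gv))
    stop("contrast group absent from sample metadata: ",
         paste(setdiff(contrast, gv), collapse = ", "))
  sel <- gv %in% contrast
  sf <- sizeFactors(rc)
  if (is.null(sf)) sf <- rep(1, ncol(rc))
  nbCore(SummarizedExperiment::assay(rc, "counts")[, sel, drop = FALSE],
         sf[sel], factor(gv[sel], levels = contrast),
         dispersion = dispersion, priorDf = priorDf)
}

#' Differential-expression table from a count matrix
#'
#' Convenience wrapper running the NB engine on genes-as-rows counts and
#' returning a DE table (gene, log2FC, raw_p, adj_p, chromosome when gene
#' annotation is supplied).
#'
#' @param counts genes x samples matrix with gene rownames
#' @param group factor/character of sample groups
#' @param contrast length-2 character (group1, group2)
#' @param genes optional GRanges with \code{gene_id} metadata, used to attach
#'   chromosomes
#' @param sizeFactors optional; defaults to median-of-ratios on all genes
#' @param dispersion passed to the engine
#' @return data.frame with columns gene_id, log2FC, raw_p, adj_p and
#'   optionally chromosome
#' @export
deTable <- function(counts, group, contrast, genes = NULL,
                    sizeFactors = NULL, dispersion = "moments") {
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  res <- nbCore(counts, sizeFactors, factor(group, levels = contrast),
                dispersion = dispersion)
  out <- data.frame(gene_id = rownames(counts), log2FC = res$log2FC,
                    raw_p = res$raw_p, adj_p = res$adj_p,
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    m <- match(out$gene_id, mcols(genes)$gene_id)
    out$chromosome <- as.character(seqnames(genes))[m]
  }
  out
}

#' Build the cell-type-specific enhancer catalogue
#'
#' Differential test of NeuN+ vs NeuN- H3K27ac counts over one region
#' universe; regions below the p cutoff with higher normalized NeuN+ signal
#' are labelled neuronal, higher NeuN- glial, all others excluded. The test
#' defaults to the exact conditional Poisson mode, matching the Poisson
#' framework in which the very stringent cell-type cutoff (1e-15) is
#' meaningful.
#'
#' @param neunPos,neunNeg \linkS4class{RegionCounts} over the same regions
#'   (NeuN+ and NeuN- samples)
#' @param pCutoff raw p-value cutoff (default 1e-15)
#' @param adjusted use BH-adjusted instead of raw p-values
#' @param dispersion engine mode, default \code{"exact"}
#' @return an \linkS4class{EnhancerCatalogue}
#' @export
buildEnhancerCatalogue <- function(neunPos, neunNeg, pCutoff = 1e-15,
                                   adjusted = FALSE, dispersion = "exact") {
  if (length(rowRanges(neunPos)) != length(rowRanges(neunNeg)) ||
      any(rowRanges(neunPos) != rowRanges(neunNeg)))
    stop("region universes differ between fractions")
  counts <- cbind(SummarizedExperiment::assay(neunPos, "counts"),
                  SummarizedExperiment::assay(neunNeg, "counts"))
  group <- rep(c("neun_pos", "neun_neg"),
               c(ncol(neunPos), ncol(neunNeg)))
  sf <- c(sizeFactors(neunPos), sizeFactors(neunNeg))
  if (is.null(sf) || length(sf) != ncol(counts))
    sf <- computeSizeFactors(counts)
  res <- nbCore(counts, sf, factor(group, levels = c("neun_neg", "neun_pos")),
                dispersion = dispersion)
  p <- if (adjusted) res$adj_p else res$raw_p
  sel <- !is.na(p) & p < pCutoff
  regions <- granges(rowRanges(neunPos))[sel]
  lab <- ifelse(res$log2FC[sel] > 0, "neuronal", "glial")
  mcols(regions)$label <- lab
  mcols(regions)$log2FC <- res$log2FC[sel]
  mcols(regions)$raw_p <- res$raw_p[sel]
  EnhancerCatalogue(regions, provenance = list(
    contrast = "neun_pos_vs_neun_neg", pCutoff = pCutoff,
    adjusted = adjusted, dispersion = dispersion))
}
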