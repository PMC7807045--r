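#' Island-calling parameters
#'
#' Window/gap/E-value parameters of the broad-domain caller. Per-mark
#' defaults: 200-bp windows for all marks with gap 1000 bp (H3K27ac), 600 bp
#' (RNAPII) or 1400 bp (H3K27me3), and E-value 0.003.
#'
#' @param windowBp scoring window in bp
#' @param gapBp maximum ineligible gap bridged inside an island; must be a
#'   multiple of \code{windowBp}
#' @param evalue expected number of false islands genome-wide under the null
#' @param eligibilityP per-window Poisson upper-tail cutoff
#' @param mark convenience: one of \code{"h3k27ac"}, \code{"rnapii"},
#'   \code{"h3k27me3"} sets the per-mark default gap
#' @return list of validated parameters
#' @export
islandParams <- function(windowBp = 200L, gapBp = NULL, evalue = 0.003,
                         eligibilityP = 0.05,
                         mark = c("h3k27ac", "rnapii", "h3k27me3")) {
  mark <- match.arg(mark)
  if (is.null(gapBp))
    gapBp <- switch(mark, h3k27ac = 1000L, rnapii = 600L, h3k27me3 = 1400L)
  windowBp <- as.integer(windowBp); gapBp <- as.integer(gapBp)
  if (gapBp %% windowBp != 0L)
    stop("gapBp must be a multiple of windowBp")
  if (evalue <= 0) stop("evalue must be > 0")
  list(windowBp = windowBp, gapBp = gapBp, evalue = evalue,
       eligibilityP = eligibilityP, mark = mark)
}

#' Global Poisson background of a track
#'
#' Expected reads per window under a uniform background: total reads divided
#' by the number of windows in the effective genome.
#'
#' @param track a \linkS4class{SignalTrack}
#' @param windowBp window size in bp
#' @return background rate lambda (reads per window)
#' @export
estimateBackground <- function(track, windowBp) {
  tot <- sum(unlist(trackValues(track), use.names = FALSE))
  if (tot == 0) stop("empty track: no reads to estimate background from")
  nwin <- sum(ceiling(track@seqlengths / windowBp))
  tot / nwin
}

## Assemble islands from eligible-window indices on one chromosome.
## Eligible windows separated by <= gapWin ineligible windows join one
## island. Returns a list of integer index vectors (members per island).
assembleRuns <- function(idx, gapWin) {
  if (!length(idx)) return(list())
  grp <- cumsum(c(1L, diff(idx) > gapWin + 1L))
  unname(split(idx, grp))
}

#' Call enriched islands on a binned track
#'
#' SICER-style broad-domain detection: windows are eligible when their
#' Poisson upper tail P(X >= count; lambda) falls below
#' \code{eligibilityP}; islands are maximal runs of eligible windows
#' bridging up to \code{gapBp} of ineligible windows; the island score is the
#' sum of -log Poisson probabilities of its eligible member windows; islands
#' are retained when their score exceeds the threshold at which the expected
#' number of equal-or-higher-scoring islands under a seeded Monte-Carlo
#' null drawn from the fitted Poisson background is at most \code{evalue}
#' (sampling the background model rather than permuting the observed counts
#' keeps the null threshold independent of how much of the genome is
#' genuinely enriched). When \code{shuffles * evalue < 1} the number of
#' Monte-Carlo rounds is raised to \code{ceiling(1/evalue)} so the
#' requested E-value is resolvable.
#'
#' @param track a raw \linkS4class{SignalTrack} of counts
#' @param params parameters from \code{\link{islandParams}}
#' @param control optional control (input) track; lambda is then taken from
#'   the control scaled to the treatment library size
#' @param shuffles permutation count for the E-value null
#' @param seed RNG seed for the permutation null
#' @return GRanges of islands with metadata columns \code{score},
#'   \code{nWindows}, \code{count} and \code{lambda}
#' @export
callIslands <- function(track, params = islandParams(), control = NULL,
                        shuffles = 20L, seed = 1L) {
  w <- params$windowBp
  if (w %% binSize(track) != 0L)
    stop("window size incompatible with track bin size")
  tr <- rebinTrack(track, w)
  if (sum(unlist(trackValues(tr), use.names = FALSE)) == 0) {
    gr <- GRanges()
    metadata(gr) <- list(lambda = 0, threshold = 0, params = params)
    return(gr)
  }
  lambda <- if (is.null(control)) {
    estimateBackground(tr, w)
  } else {
    estimateBackground(rebinTrack(control, w), w) *
      libSize(track) / libSize(control)
  }
  gapWin <- params$gapBp %/% w
  chroms <- names(trackValues(tr))
  counts <- lapply(trackValues(tr), round)
  ## eligibility threshold on counts: smallest c with P(X >= c) < p
  cstar <- qpoisUpper(lambda, params$eligibilityP)
  scoreOf <- function(v) -dpois(v, lambda, log = TRUE)

  obs <- list()
  for (chr in chroms) {
    v <- counts[[chr]]
    idx <- which(v >= cstar)
    for (mem in assembleRuns(idx, gapWin)) {
      obs[[length(obs) + 1L]] <- list(
        chr = chr, from = mem[1], to = mem[length(mem)],
        score = sum(scoreOf(v[mem])), n = length(mem),
        count = sum(v[mem]))
    }
  }
  threshold <- islandScoreThreshold(counts, cstar, scoreOf, gapWin,
                                    params$evalue, shuffles, seed, lambda)
  keep <- vapply(obs, function(o) o$score > threshold, TRUE)
  obs <- obs[keep]
  if (!length(obs)) {
    gr <- GRanges()
  } else {
    gr <- GRanges(
      vapply(obs, `[[`, "", "chr"),
      IRanges((vapply(obs, `[[`, 0, "from") - 1) * w + 1,
              pmin(vapply(obs, `[[`, 0, "to") * w,
                   track@seqlengths[vapply(obs, `[[`, "", "chr")])))
    mcols(gr)$score <- vapply(obs, `[[`, 0, "score")
    mcols(gr)$nWindows <- as.integer(vapply(obs, `[[`, 0, "n"))
    mcols(gr)$count <- vapply(obs, `[[`, 0, "count")
    mcols(gr)$lambda <- lambda
  }
  metadata(gr) <- list(lambda = lambda, threshold = threshold,
                       params = params)
  gr
}

qpoisUpper <- function(lambda, p) {
  c <- 0L
  while (ppois(c - 1L, lambda, lower.tail = FALSE) >= p) c <- c + 1L
  c
}

## Monte-Carlo null for the island score threshold, drawn from the fitted
## Poisson background: eligible-window positions are scattered uniformly
## over the concatenated genome (respecting chromosome breaks) with
## background eligibility probability, their counts drawn from the
## background tail, and null islands assembled.  The threshold is the score
## whose pooled null exceedance count corresponds to an expected <= evalue
## islands per genome; sampling from the background model (rather than
## permuting the observed counts) keeps the null uncontaminated by genuine
## enrichment.
islandScoreThreshold <- function(counts, cstar, scoreOf, gapWin, evalue,
                                 shuffles, seed, lambda) {
  lens <- lengths(counts)
  N <- sum(lens)
  breaks <- cumsum(lens)
  pElig <- ppois(cstar - 1L, lambda, lower.tail = FALSE)
  if (pElig <= 0) return(0)
  ## background tail counts c*, c*+1, ... covering all but 1e-12 tail mass
  cmax <- cstar
  while (ppois(cmax, lambda, lower.tail = FALSE) > 1e-12 * pElig)
    cmax <- cmax + 1L
  tailCounts <- seq.int(cstar, cmax)
  tailProb <- dpois(tailCounts, lambda)
  tailProb <- tailProb / sum(tailProb)
  tailScore <- scoreOf(tailCounts)
  B <- max(shuffles, ceiling(1 / evalue))
  nullScores <- withSeed(seed, function() {
    res <- vector("list", B)
    for (b in seq_len(B)) {
      k <- stats::rbinom(1L, N, pElig)
      if (k == 0L) { res[[b]] <- numeric(0); next }
      pos <- sort.int(sample.int(N, k))
      sc <- tailScore[sample.int(length(tailCounts), k, replace = TRUE,
                                 prob = tailProb)]
      chrIdx <- findInterval(pos - 1L, breaks) + 1L
      newGrp <- c(TRUE, diff(pos) > gapWin + 1L | diff(chrIdx) != 0L)
      grp <- cumsum(newGrp)
      res[[b]] <- as.numeric(rowsum(sc, grp))
    }
    unlist(res, use.names = FALSE)
  })
  allowed <- floor(B * evalue)
  srt <- sort(nullScores, decreasing = TRUE)
  if (length(srt) <= allowed) return(0)
  srt[allowed + 1L]
}

#' High-confidence islands across replicates
#'
#' Retains islands (from any replicate) that overlap, by at least 1 bp, an
#' island in every replicate list, and merges the retained set.
#'
#' @param replicates list (length >= 2) of island GRanges
#' @return merged GRanges of high-confidence islands
#' @export
highConfidenceIslands <- function(replicates) {
  if (length(replicates) < 2L) stop("at least 2 replicate lists required")
  kept <- lapply(seq_along(replicates), function(i) {
    gr <- replicates[[i]]
    if (!length(gr)) return(GRanges())
    inAll <- rep(TRUE, length(gr))
    for (j in seq_along(replicates)) {
      if (j == i) next
      inAll <- inAll & overlapsAny(gr, replicates[[j]],
                                   ignore.strand = TRUE)
    }
    granges(gr[inAll])
  })
  reduce(do.call(c, kept), ignore.strand = TRUE)
}
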