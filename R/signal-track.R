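#' Rebin a track to a coarser bin size
#'
#' Sums bin values into windows; \code{newBin} must be a multiple of the
#' track's bin size.
#'
#' @param track a \linkS4class{SignalTrack}
#' @param newBin target bin size in bp
#' @return a \linkS4class{SignalTrack} at the new bin size
#' @export
rebinTrack <- function(track, newBin) {
  bs <- binSize(track)
  newBin <- as.integer(newBin)
  if (newBin == bs) return(track)
  if (newBin %% bs != 0) stop("newBin must be a multiple of the bin size")
  k <- newBin %/% bs
  vals <- lapply(names(trackValues(track)), function(chr) {
    v <- trackValues(track)[[chr]]
    nOut <- ceiling(track@seqlengths[[chr]] / newBin)
    grp <- rep(seq_len(nOut), each = k, length.out = length(v))
    as.numeric(tapply(v, grp, sum))
  })
  names(vals) <- names(trackValues(track))
  SignalTrack(vals, newBin, track@seqlengths,
              normalization = normalizationState(track),
              libSize = libSize(track))
}

#' Normalize a track to 1x genome coverage
#'
#' Scales values so the genome-wide mean bin value equals 1 (uniform signal
#' becomes a flat track of ones). One-way: the result is stamped
#' \code{rpgc_1x} and cannot be re-normalized back to \code{raw}.
#'
#' @param track a raw or background-equalized \linkS4class{SignalTrack}
#' @return a \linkS4class{SignalTrack} in state \code{rpgc_1x}
#' @export
normalizeTrack1x <- function(track) {
  if (normalizationState(track) == "rpgc_1x") return(track)
  tot <- sum(unlist(trackValues(track), use.names = FALSE))
  nbins <- sum(lengths(trackValues(track)))
  if (tot == 0) stop("cannot normalize an all-zero track")
  f <- nbins / tot
  vals <- lapply(trackValues(track), function(v) v * f)
  SignalTrack(vals, binSize(track), track@seqlengths,
              normalization = "rpgc_1x", libSize = libSize(track))
}

#' Scale a track by a per-sample factor (background equalization)
#'
#' Divides all values by a size factor estimated from background regions
#' (see \code{\link{computeSizeFactors}}); the result is stamped
#' \code{background_equalized}.
#'
#' @param track a raw \linkS4class{SignalTrack}
#' @param sizeFactor positive scalar
#' @return a \linkS4class{SignalTrack} in state \code{background_equalized}
#' @export
equalizeBackground <- function(track, sizeFactor) {
  if (sizeFactor <= 0) stop("size factor must be positive")
  vals <- lapply(trackValues(track), function(v) v / sizeFactor)
  SignalTrack(vals, binSize(track), track@seqlengths,
              normalization = "background_equalized",
              libSize = libSize(track))
}

#' Region read counts from binned tracks
#'
#' Sums bin values over each region for each track (bins weighted by their
#' overlap fraction with the region), yielding the regions x samples count
#' matrix used by the differential stage.
#'
#' @param tracks named list of \linkS4class{SignalTrack}s on the same genome
#' @param regions GRanges
#' @param sampleData optional per-sample metadata data.frame
#' @return a \linkS4class{RegionCounts}
#' @export
regionCounts <- function(tracks, regions, sampleData = NULL) {
  chrOf <- as.character(seqnames(regions))
  counts <- vapply(tracks, function(tr) {
    bs <- binSize(tr)
    css <- lapply(trackValues(tr), function(v) c(0, cumsum(v)))
    vapply(seq_along(regions), function(i) {
      v <- trackValues(tr)[[chrOf[i]]]
      if (is.null(v)) return(0)
      segmentSums(v, bs, start(regions)[i] - 1L, end(regions)[i],
                  cs = css[[chrOf[i]]])
    }, 0)
  }, numeric(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(NULL, names(tracks)))
  RegionCounts(regions, counts, sampleData = sampleData)
}

## Integral of a piecewise-constant binned signal over [from, to) in bp
## coordinates (0-based), counting each bin's value as spread uniformly over
## its bp span. Exact for bin-aligned spans. `cs` is the precomputed
## c(0, cumsum(vals)) (pass it to amortize repeated queries).
segmentSums <- function(vals, binSize, from, to, cs = NULL) {
  n <- length(vals)
  from <- max(0, from); to <- min(n * binSize, to)
  if (to <= from) return(0)
  if (is.null(cs)) cs <- c(0, cumsum(vals))
  integ <- function(x) {
    b <- x / binSize
    lo <- floor(b)
    cs[lo + 1] + (b - lo) * vals[pmin(lo + 1, n)]
  }
  integ(to) - integ(from)
}

## Mean signal over consecutive output bins defined by bp breakpoints
## (vectorized over the breakpoints; `cs` as in segmentSums).
segmentMeans <- function(vals, binSize, breaks, cs = NULL) {
  n <- length(vals)
  if (is.null(cs)) cs <- c(0, cumsum(vals))
  x <- pmin(pmax(breaks, 0), n * binSize)
  b <- x / binSize
  lo <- floor(b)
  I <- cs[lo + 1] + (b - lo) * vals[pmin(lo + 1, n)]
  w <- diff(x)
  out <- diff(I) / (w / binSize)
  out[w <= 0] <- NA_real_
  out
}
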