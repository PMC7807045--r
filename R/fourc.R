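#' Build a restriction-fragment map from genome sequence
#'
#' Fragments are delimited by consecutive first-cutter sites; the 4-bp site
#' is assigned to the downstream fragment (each internal fragment starts at
#' a site start, matching an enzyme cutting 5' of its recognition sequence).
#' Each fragment is annotated with second-cutter presence and the offset of
#' the first internal second-cutter site; fragments without one are blind.
#' A chromosome with no first-cutter site yields a single fragment spanning
#' it, flagged blind when it also lacks a second site.
#'
#' @param genome DNAStringSet (or named character vector of sequences)
#' @param firstSite first-cutter recognition site (default GATC, DpnII)
#' @param secondSite second-cutter recognition site (default GTAC, Csp6I)
#' @return a \linkS4class{FragmentMap}
#' @export
buildFragmentMap <- function(genome, firstSite = "GATC",
                             secondSite = "GTAC") {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  if (nchar(firstSite) != 4L || nchar(secondSite) != 4L)
    stop("restriction sites must be 4-bp literals")
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  all <- GRanges()
  for (chr in names(genome)) {
    seq <- genome[[chr]]
    len <- length(seq)
    s1 <- start(matchPattern(firstSite, seq))
    bounds <- unique(c(1L, s1, len + 1L))
    bounds <- sort(bounds[bounds <= len + 1L])
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1L
    keep <- ends >= starts
    starts <- starts[keep]; ends <- ends[keep]
    s2 <- start(matchPattern(secondSite, seq))
    fr <- GRanges(chr, IRanges(starts, ends))
    bin <- findInterval(s2, starts)
    firstOff <- rep(NA_integer_, length(starts))
    nSecond <- tabulate(bin, nbins = length(starts))
    if (length(s2)) {
      firstPos <- tapply(s2, bin, min)
      firstOff[as.integer(names(firstPos))] <-
        as.integer(firstPos) - starts[as.integer(names(firstPos))]
    }
    mcols(fr)$nSecond <- nSecond
    mcols(fr)$firstSecondOffset <- firstOff
    mcols(fr)$blind <- nSecond == 0L
    all <- c(all, fr)
  }
  new("FragmentMap", fragments = all, firstSite = firstSite,
      secondSite = secondSite)
}

#' Check bait/primer design criteria for a fragment
#'
#' Applies the two distance criteria: first-cutter site to the consecutive
#' second-cutter site must exceed 350 bp, and the first-cutter to
#' first-cutter span (the fragment length) must lie strictly between 500 and
#' 1500 bp. Blind fragments fail outright.
#'
#' @param map a \linkS4class{FragmentMap}
#' @param baitFragment fragment index within the map
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector of failed criteria, empty on pass)
#' @export
checkBaitDesign <- function(map, baitFragment) {
  fr <- fragments(map)
  if (baitFragment < 1L || baitFragment > length(fr))
    stop("bait fragment not in map")
  f <- fr[baitFragment]
  reasons <- character(0)
  if (mcols(f)$blind) {
    reasons <- "blind fragment: no second-cutter site"
  } else {
    if (mcols(f)$firstSecondOffset <= 350)
      reasons <- c(reasons,
                   "first-to-second cutter distance <= 350 bp")
    if (width(f) <= 500)
      reasons <- c(reasons, "fragment length <= 500 bp")
    if (width(f) >= 1500)
      reasons <- c(reasons, "fragment length >= 1500 bp")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Quantile-normalize a set of 4C profiles over one bait
#'
#' Standard quantile normalization across samples over the scored (non
#' excluded) fragments: sorted values are replaced by the rank-wise mean
#' across samples (tied observations receive the average of the reference
#' quantiles they span), making every sample's score distribution identical
#' (exactly so for tie-free data) while preserving within-sample rank
#' order.
#'
#' @param profiles list of \linkS4class{FourCProfile}s with identical
#'   fragment universes and excluded sets
#' @return list of profiles with normalized \code{score}
#' @export
quantileNormalize <- function(profiles) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (length(p@fragments) != length(ref@fragments) ||
        any(p@fragments != ref@fragments))
      stop("fragment universes differ across profiles")
    if (!identical(p@excluded, ref@excluded))
      stop("excluded fragment sets differ across profiles")
  }
  scored <- setdiff(seq_along(ref@fragments), ref@excluded)
  mat <- vapply(profiles, function(p) p@score[scored],
                numeric(length(scored)))
  refDist <- rowMeans(apply(mat, 2L, sort))
  nm <- apply(mat, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    (refDist[floor(r)] + refDist[ceiling(r)]) / 2
  })
  lapply(seq_along(profiles), function(j) {
    p <- profiles[[j]]
    p@score[scored] <- nm[, j]
    p
  })
}

## Centred running mean with shrunken symmetric edge windows.
runningMeanShrunk <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
  }
  out
}

#' Smooth a 4C profile by a running mean over fragments
#'
#' Centred running mean over the scored fragments in fragment order (window
#' default 21 fragments); edges use shrunken symmetric windows and excluded
#' bait-proximal fragments are skipped (they stay NA).
#'
#' @param profile a \linkS4class{FourCProfile} with normalized scores
#' @param window odd window size in fragments
#' @return the profile with smoothed \code{score}
#' @export
smoothProfile <- function(profile, window = 21L) {
  if (window %% 2L == 0L) stop("window must be odd")
  scored <- setdiff(seq_along(profile@fragments), profile@excluded)
  if (window > length(scored))
    stop("window exceeds the number of scored fragments")
  sm <- runningMeanShrunk(profile@score[scored], window)
  profile@score[scored] <- sm
  profile
}

## Isotonic monotone-decay background per side of the bait:
## non-increasing with distance from the bait, fitted separately up- and
## downstream on the scored fragments.
isotonicBackground <- function(score, scoredIdx, baitIndex) {
  bg <- rep(NA_real_, length(score))
  up <- scoredIdx[scoredIdx < baitIndex]
  dn <- scoredIdx[scoredIdx > baitIndex]
  if (length(up) > 1) {
    fit <- isoreg(seq_along(up), score[up])  # non-decreasing toward bait
    bg[up] <- fit$yf
  } else if (length(up) == 1) bg[up] <- score[up]
  if (length(dn) > 1) {
    ## non-increasing away from the bait: fit non-decreasing on the
    ## reversed order, then reverse back
    fit <- isoreg(seq_along(dn), rev(score[dn]))
    bg[dn] <- rev(fit$yf)
  } else if (length(dn) == 1) bg[dn] <- score[dn]
  bg
}

#' Call interacting regions on smoothed 4C profiles
#'
#' Per sample, the background expectation is fitted as a monotonically
#' non-increasing function of distance from the bait (isotonic regression,
#' separately up- and downstream of the bait); fragments whose smoothed
#' score exceeds the background by more than the \code{thresholdQuantile}
#' quantile of the positive-side residual spread are candidates; candidates
#' within \code{mergeGap} fragments are merged and regions shorter than
#' \code{minFragments} dropped. Reproducible regions are the intersected
#' extents of regions present in every sample of a condition.
#'
#' @param profiles named list of smoothed \linkS4class{FourCProfile}s
#'   (same bait)
#' @param conditions character/factor assigning each profile to a condition
#' @param thresholdQuantile genome-wide null quantile defining exceedance
#'   (default 0.99): the threshold is set so that, under a Gaussian null for
#'   the smoothed log-residuals, the probability of any exceedance along the
#'   profile is 1 - thresholdQuantile (Sidak correction over the effective
#'   number of independent smoothing windows)
#' @param effectiveWindow smoothing window used upstream (sets the effective
#'   independence length of the residuals)
#' @param mergeGap maximum fragment gap merged into one region
#' @param minFragments minimum fragments per region
#' @return list with \code{perSample} (list of IRanges of candidate regions,
#'   fragment indices) and \code{reproducible} (per condition, IRanges of
#'   regions called in all samples)
#' @export
callInteractions <- function(profiles, conditions,
                             thresholdQuantile = 0.99,
                             effectiveWindow = 21L, mergeGap = 2L,
                             minFragments = 3L) {
  stopifnot(length(profiles) == length(conditions))
  perSample <- lapply(profiles, function(p) {
    if (!(p@baitIndex %in% seq_along(p@fragments)))
      stop("bait fragment not in profile")
    ## the bait fragment itself never counts as an interaction candidate
    scored <- setdiff(seq_along(p@fragments), c(p@excluded, p@baitIndex))
    ## log scale: 4C noise is multiplicative, so residuals of the raw
    ## scores grow with proximity to the bait; log-scores make the
    ## exceedance threshold scale-free along the profile
    lsc <- p@score
    lsc[scored] <- log1p(pmax(p@score[scored], 0))
    bg <- isotonicBackground(lsc, scored, p@baitIndex)
    res <- lsc[scored] - bg[scored]
    ## exceedance threshold: noise spread estimated from trimmed first
    ## differences of the residuals (differencing removes broad genuine
    ## interactions, so a real loop cannot inflate its own threshold),
    ## rescaled by the smoothing factor, with a Sidak correction for the
    ## number of effectively independent smoothed windows so that a null
    ## profile rarely produces any candidate at all
    dd <- diff(res)
    dd <- dd[abs(dd) <= quantile(abs(dd), 0.95)]
    sp <- max(sd(dd) * sqrt(effectiveWindow / 2), .Machine$double.eps)
    m <- max(1, ceiling(length(res) / effectiveWindow))
    thr <- stats::qnorm(thresholdQuantile^(1 / m)) * sp
    cand <- scored[res > thr]
    if (!length(cand)) return(IRanges())
    grp <- cumsum(c(1L, diff(cand) > mergeGap + 1L))
    spans <- vapply(split(cand, grp),
                    function(ix) c(ix[1], ix[length(ix)]), c(0, 0))
    ir <- IRanges(spans[1, ], spans[2, ])
    ir[width(ir) >= minFragments]
  })
  names(perSample) <- names(profiles)
  reproducible <- lapply(split(seq_along(profiles), conditions),
    function(ix) {
      Reduce(function(a, b) {
        hits <- findOverlaps(a, b)
        if (!length(hits)) return(IRanges())
        pintersect(a[queryHits(hits)], b[subjectHits(hits)])
      }, perSample[ix])
    })
  list(perSample = perSample, reproducible = reproducible)
}

#' Differential interaction test over called regions
#'
#' Per region, each sample's mean quantile-normalized score over the member
#' fragments is computed; the two conditions are compared with a two-tailed
#' t test (paired across declared pairs when \code{paired}), BH-adjusted
#' across regions. Degenerate paired tests (zero variance of the
#' differences) fall back to the unpaired Welch test with a warning.
#'
#' @param regions IRanges of member-fragment index ranges
#' @param profiles named list of \linkS4class{FourCProfile}s (normalized,
#'   unsmoothed scores)
#' @param conditions length-2-level factor assigning profiles to conditions
#' @param paired treat samples as paired in order within condition
#' @return data.frame per region: start/end fragment, per-condition means,
#'   t, raw_p, adj_p
#' @export
differentialInteraction <- function(regions, profiles, conditions,
                                    paired = FALSE) {
  conditions <- factor(conditions)
  if (nlevels(conditions) != 2L) stop("exactly 2 conditions required")
  if (any(table(conditions) < 2L))
    stop("each condition needs >= 2 samples")
  means <- vapply(profiles, function(p) {
    vapply(seq_along(regions), function(i) {
      ix <- seq(start(regions)[i], end(regions)[i])
      mean(p@score[ix], na.rm = TRUE)
    }, 0)
  }, numeric(length(regions)))
  means <- matrix(means, nrow = length(regions))
  g1 <- which(conditions == levels(conditions)[1])
  g2 <- which(conditions == levels(conditions)[2])
  res <- lapply(seq_along(regions), function(i) {
    x <- means[i, g1]; y <- means[i, g2]
    if (all(x == y)) return(list(t = 0, p = 1))
    if (paired) {
      d <- y - x
      if (sd(d) == 0) {
        warning("zero-variance paired differences; ",
                "falling back to the unpaired Welch test")
      } else {
        tt <- t.test(y, x, paired = TRUE)
        return(list(t = unname(tt$statistic), p = tt$p.value))
      }
    }
    if (sd(x) == 0 && sd(y) == 0)
      return(list(t = if (mean(x) == mean(y)) 0 else Inf,
                  p = if (mean(x) == mean(y)) 1 else 0))
    tt <- t.test(y, x)
    list(t = unname(tt$statistic), p = tt$p.value)
  })
  pv <- vapply(res, `[[`, 0, "p")
  data.frame(
    startFragment = start(regions), endFragment = end(regions),
    mean1 = rowMeans(means[, g1, drop = FALSE]),
    mean2 = rowMeans(means[, g2, drop = FALSE]),
    t = vapply(res, `[[`, 0, "t"),
    raw_p = pv, adj_p = adjustPvalues(pv, "BH"))
}
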