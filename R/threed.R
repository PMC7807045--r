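#' Convert 4C signal to distance restraints
#'
#' Per (bait, bead): bead signal is the mean normalized score of its member
#' fragments; the target distance is the inverse-power transform
#' d proportional to s^(-1/alpha), affinely rescaled so the observed signal
#' range maps onto [dMin, dMax] model units. Beads without scored fragments
#' (or with non-positive signal) contribute no restraint.
#'
#' @param profiles named list of \linkS4class{FourCProfile}s, one per bait
#' @param chain a \linkS4class{BeadChain} covering the profiles' locus
#' @param alpha decay exponent of the contact model
#' @param dMin,dMax model-unit range of the target distances. The default
#'   \code{dMin = NULL} rescales proportionally (the largest transformed
#'   value maps to \code{dMax}, ratios preserved — exact for a true
#'   power-law contact model); supplying \code{dMin} switches to an affine
#'   rescale of the observed range onto [dMin, dMax]
#' @param weight uniform restraint weight
#' @return data.frame restraint set: baitBead, bead, target, weight
#' @export
signalToRestraints <- function(profiles, chain, alpha = 1, dMin = NULL,
                               dMax = 10, weight = 1) {
  fpb <- chain@fragmentsPerBead
  rows <- list()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    nFrag <- length(p@fragments)
    beadOf <- pmin((seq_len(nFrag) - 1L) %/% fpb + 1L, chain@nBeads)
    baitBead <- beadOf[p@baitIndex]
    sig <- tapply(p@score, beadOf, mean, na.rm = TRUE)
    for (b in seq_len(chain@nBeads)) {
      s <- sig[[as.character(b)]]
      if (b == baitBead || is.null(s) || is.na(s) || s <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        baitBead = baitBead, bead = b, x = s^(-1 / alpha))
    }
  }
  if (!length(rows)) stop("no usable restraints")
  rs <- do.call(rbind, rows)
  rng <- range(rs$x)
  rs$target <- if (is.null(dMin)) {
    rs$x * dMax / rng[2]
  } else if (rng[1] == rng[2]) {
    rep((dMin + dMax) / 2, nrow(rs))
  } else {
    dMin + (rs$x - rng[1]) / (rng[2] - rng[1]) * (dMax - dMin)
  }
  rs$weight <- weight
  rs[, c("baitBead", "bead", "target", "weight")]
}

accumRows <- function(values, index, n) {
  out <- numeric(n)
  tmp <- rowsum(values, index)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

makeObjective <- function(n, restraints, cMin, cMax, kConn, rEv, kEv) {
  rA <- restraints$baitBead; rB <- restraints$bead
  rT <- restraints$target; rW <- restraints$weight
  consA <- seq_len(n - 1L); consB <- consA + 1L
  pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- pairIdx[, 2] - pairIdx[, 1]
  evA <- pairIdx[sep >= 2L, 1]; evB <- pairIdx[sep >= 2L, 2]

  fn <- function(par) {
    x <- matrix(par, n, 3)
    dd <- function(a, b) {
      dx <- x[a, , drop = FALSE] - x[b, , drop = FALSE]
      sqrt(rowSums(dx^2)) + 1e-12
    }
    d <- dd(rA, rB)
    f <- sum(rW * (d - rT)^2)
    dc <- dd(consA, consB)
    f <- f + kConn * sum(pmax(dc - cMax, 0)^2 + pmax(cMin - dc, 0)^2)
    de <- dd(evA, evB)
    f <- f + kEv * sum(pmax(rEv - de, 0)^2)
    f
  }
  gr <- function(par) {
    x <- matrix(par, n, 3)
    g <- matrix(0, n, 3)
    addTerm <- function(a, b, coef) {
      dx <- x[a, , drop = FALSE] - x[b, , drop = FALSE]
      for (j in 1:3) {
        g[, j] <<- g[, j] + accumRows(coef * dx[, j], a, n) -
          accumRows(coef * dx[, j], b, n)
      }
    }
    dd <- function(a, b) {
      dx <- x[a, , drop = FALSE] - x[b, , drop = FALSE]
      sqrt(rowSums(dx^2)) + 1e-12
    }
    d <- dd(rA, rB)
    addTerm(rA, rB, 2 * rW * (d - rT) / d)
    dc <- dd(consA, consB)
    addTerm(consA, consB,
            2 * kConn * (pmax(dc - cMax, 0) - pmax(cMin - dc, 0)) / dc)
    de <- dd(evA, evB)
    addTerm(evA, evB, -2 * kEv * pmax(rEv - de, 0) / de)
    as.numeric(g)
  }
  list(fn = fn, gr = gr)
}

#' Fit a 3D bead model from distance restraints
#'
#' Minimizes the sum of weighted squared restraint violations plus harmonic
#' connectivity walls on consecutive-bead distances and a soft
#' excluded-volume lower wall on all non-adjacent pairs, by L-BFGS-B from
#' multiple seeded random-walk initializations; the lowest-objective restart
#' wins. Deterministic under a fixed seed.
#'
#' @param restraints data.frame from \code{\link{signalToRestraints}}
#' @param chain a \linkS4class{BeadChain}
#' @param seed RNG seed
#' @param nRestarts number of restarts (default 20)
#' @param cMin,cMax connectivity wall bounds (model units); defaults scale
#'   with the typical consecutive-bead spacing implied by the restraints
#' @param kConn,kEv wall stiffness of connectivity / excluded volume
#' @param evRadius excluded-volume radius; default half the typical spacing
#' @param maxit L-BFGS-B iteration cap per restart
#' @return a \linkS4class{BeadModel}
#' @export
fitBeadModel <- function(restraints, chain, seed = 1L, nRestarts = 20L,
                         cMin = NULL, cMax = NULL, kConn = 1, kEv = 0.2,
                         evRadius = NULL, maxit = 500L) {
  n <- chain@nBeads
  if (length(unique(restraints$baitBead)) < 4L)
    stop(">= 4 baits with restraints are required")
  ## typical consecutive spacing: median |target difference| between beads
  ## adjacent in the chain, per bait (a lower bound via triangle inequality)
  spac <- unlist(lapply(split(restraints, restraints$baitBead),
    function(df) {
      df <- df[order(df$bead), ]
      abs(diff(df$target))[diff(df$bead) == 1L]
    }), use.names = FALSE)
  spacing <- max(median(spac, na.rm = TRUE), 1e-3)
  if (is.null(cMin)) cMin <- 0.1 * spacing
  if (is.null(cMax)) cMax <- 4 * spacing
  if (is.null(evRadius)) evRadius <- 0.5 * spacing
  obj <- makeObjective(n, restraints, cMin, cMax, kConn, evRadius, kEv)
  best <- NULL
  withSeed(seed, function() {
    for (r in seq_len(nRestarts)) {
      steps <- matrix(rnorm(3 * n), n, 3)
      steps <- steps / sqrt(rowSums(steps^2)) * spacing
      init <- apply(steps, 2, cumsum)
      fit <- optim(as.numeric(init), obj$fn, obj$gr, method = "L-BFGS-B",
                   control = list(maxit = maxit))
      if (is.null(best) || fit$value < best$value) {
        best <<- fit
        best$restart <<- r
      }
    }
  })
  if (!is.finite(best$value)) stop("optimization failed to converge")
  coords <- matrix(best$par, n, 3)
  coords <- sweep(coords, 2, colMeans(coords))
  new("BeadModel", coords = coords, objective = best$value,
      seed = as.integer(seed), restart = as.integer(best$restart),
      chain = chain)
}

#' Virtual Hi-C distance matrix of a bead model
#'
#' @param model a \linkS4class{BeadModel} (or a beads x 3 coordinate matrix)
#' @return a \linkS4class{VirtualHiC}
#' @export
virtualHiC <- function(model) {
  coords <- if (is(model, "BeadModel")) beadCoords(model) else
    as.matrix(model)
  VirtualHiC(as.matrix(dist(coords)))
}

#' Multi-scale insulation score and boundary detection
#'
#' Contact proxy c = 1/(d + eps) with eps = 1e-6 times the median off
#' diagonal distance. For window size b, the insulation at position k is the
#' mean contact over the b x b square crossing k (pairs i in [k-b, k-1],
#' j in [k, k+b-1]); defined only where the full window fits. Each window
#' size is z-scored over its defined positions; the aggregate profile
#' averages the z-scores over b (on the common support) and boundaries are
#' its local minima with prominence at least \code{prominence} times the
#' aggregate range. Boundaries mark low insulation: TAD borders.
#'
#' @param vhic a \linkS4class{VirtualHiC}
#' @param bMin,bMax window-size range in beads (defaults 4 and 30, capped at
#'   just under half the chain)
#' @param prominence minimum boundary prominence as a fraction of the
#'   aggregate range
#' @param bpPerBead genomic span per bead (for bp reporting)
#' @return an \linkS4class{InsulationProfile}
#' @export
insulationScore <- function(vhic, bMin = 4L, bMax = 30L, prominence = 0.2,
                            bpPerBead = 1e4) {
  d <- distanceMatrix(vhic)
  n <- nrow(d)
  if (bMax >= n / 2) stop("bMax must be < nBeads/2")
  if (bMin < 1L || bMin > bMax) stop("invalid window range")
  eps <- 1e-6 * median(d[upper.tri(d)])
  ct <- 1 / (d + eps)
  bs <- seq.int(bMin, bMax)
  perBin <- matrix(NA_real_, length(bs), n,
                   dimnames = list(paste0("b", bs), NULL))
  for (bi in seq_along(bs)) {
    b <- bs[bi]
    raw <- rep(NA_real_, n)
    for (k in seq.int(b + 1L, n - b + 1L)) {
      raw[k] <- mean(ct[seq.int(k - b, k - 1L), seq.int(k, k + b - 1L)])
    }
    ok <- !is.na(raw)
    mu <- mean(raw[ok]); sg <- sd(raw[ok])
    perBin[bi, ok] <- if (sg > 0) (raw[ok] - mu) / sg else 0
  }
  agg <- colMeans(perBin)
  boundaries <- localMinima(agg, prominence)
  new("InsulationProfile", perBin = perBin, aggregate = agg,
      boundaries = as.integer(boundaries), bRange = as.integer(bs),
      bpPerBead = bpPerBead)
}

## Local minima of a profile (NA-padded) with prominence filtering:
## prominence of a minimum = the smaller of the climbs to the highest point
## reached on each side before a lower value occurs.
localMinima <- function(x, promFrac) {
  ok <- which(!is.na(x))
  if (length(ok) < 3) return(integer(0))
  v <- x[ok]
  m <- length(v)
  cand <- which(vapply(seq_len(m), function(i) {
    l <- if (i > 1) v[i - 1] else Inf
    r <- if (i < m) v[i + 1] else Inf
    v[i] < l && v[i] <= r
  }, TRUE))
  if (!length(cand)) return(integer(0))
  rng <- diff(range(v))
  if (rng == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    leftMax <- if (i == 1) v[1] else {
      seg <- v[seq_len(i - 1)]
      below <- which(seg < v[i])
      if (length(below)) max(seg[seq.int(max(below) + 1L, i - 1L)]) else
        max(seg)
    }
    rightMax <- if (i == m) v[m] else {
      seg <- v[seq.int(i + 1L, m)]
      below <- which(seg < v[i])
      if (length(below)) {
        if (below[1] == 1L) v[i] else max(seg[seq_len(below[1] - 1L)])
      } else max(seg)
    }
    prom <- min(leftMax, rightMax) - v[i]
    prom >= promFrac * rng
  }, TRUE)
  ok[cand[keep]]
}

#' Match and compare TAD boundaries between two insulation profiles
#'
#' Boundaries are matched greedily by proximity (closest pairs first, up to
#' \code{maxMatch} beads apart); each match reports the signed displacement
#' in beads and bp and the difference in aggregate insulation depth;
#' unmatched boundaries are flagged.
#'
#' @param a,b \linkS4class{InsulationProfile}s over identical chains
#' @param maxMatch maximum matching distance in beads
#' @return data.frame: boundaryA, boundaryB, displacementBeads,
#'   displacementBp, depthDiff, matched
#' @export
compareBoundaries <- function(a, b, maxMatch = 5L) {
  if (length(a@aggregate) != length(b@aggregate))
    stop("profiles are over different chains")
  ba <- insulationBoundaries(a); bb <- insulationBoundaries(b)
  pairs <- expand.grid(i = seq_along(ba), j = seq_along(bb))
  pairs$d <- abs(ba[pairs$i] - bb[pairs$j])
  pairs <- pairs[pairs$d <= maxMatch, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  usedA <- usedB <- logical(0)
  rows <- list()
  takenA <- rep(FALSE, length(ba)); takenB <- rep(FALSE, length(bb))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (takenA[i] || takenB[j]) next
    takenA[i] <- TRUE; takenB[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      boundaryA = ba[i], boundaryB = bb[j],
      displacementBeads = bb[j] - ba[i],
      displacementBp = (bb[j] - ba[i]) * a@bpPerBead,
      depthDiff = b@aggregate[bb[j]] - a@aggregate[ba[i]],
      matched = TRUE)
  }
  for (i in which(!takenA))
    rows[[length(rows) + 1L]] <- data.frame(
      boundaryA = ba[i], boundaryB = NA_integer_,
      displacementBeads = NA_real_, displacementBp = NA_real_,
      depthDiff = NA_real_, matched = FALSE)
  for (j in which(!takenB))
    rows[[length(rows) + 1L]] <- data.frame(
      boundaryA = NA_integer_, boundaryB = bb[j],
      displacementBeads = NA_real_, displacementBp = NA_real_,
      depthDiff = NA_real_, matched = FALSE)
  if (!length(rows))
    return(data.frame(boundaryA = integer(0), boundaryB = integer(0),
                      displacementBeads = numeric(0),
                      displacementBp = numeric(0), depthDiff = numeric(0),
                      matched = logical(0)))
  do.call(rbind, rows)
}

#' Similarity of two virtual Hi-C matrices
#'
#' Spearman correlation of the strictly-upper-triangle distances.
#'
#' @param a,b \linkS4class{VirtualHiC}s of equal dimension
#' @return correlation coefficient
#' @export
modelSimilarity <- function(a, b) {
  da <- distanceMatrix(a); db <- distanceMatrix(b)
  if (!all(dim(da) == dim(db))) stop("dimension mismatch")
  cor(da[upper.tri(da)], db[upper.tri(db)], method = "spearman")
}
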