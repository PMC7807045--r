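#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- findOverlaps countOverlaps pintersect reduce granges
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame queryHits subjectHits metadata metadata<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData colData<-
#' @importFrom BiocGenerics sizeFactors
#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
NULL

TRACK_STATES <- c("raw", "background_equalized", "rpgc_1x")

#' Binned genome-wide signal track
#'
#' Holds per-chromosome vectors of binned read counts or normalized coverage at
#' a fixed bin size, together with the total signal and a one-way normalization
#' state (\code{raw} can become \code{background_equalized} or \code{rpgc_1x},
#' never the reverse).
#'
#' @slot values named list of non-negative numeric vectors, one per chromosome;
#'   vector length is \code{ceiling(seqlength / binSize)}
#' @slot binSize bin width in bp
#' @slot seqlengths named integer chromosome lengths in bp
#' @slot libSize total signal (for raw tracks, total mapped reads)
#' @slot normalization one of \code{raw}, \code{background_equalized},
#'   \code{rpgc_1x}
#' @export
setClass("SignalTrack", representation(
  values = "list",
  binSize = "integer",
  seqlengths = "integer",
  libSize = "numeric",
  normalization = "character"
))

setValidity("SignalTrack", function(object) {
  v <- object@values
  sl <- object@seqlengths
  if (length(v) == 0L || is.null(names(v)) || any(names(v) == ""))
    return("values must be a non-empty named list")
  if (!identical(sort(names(v)), sort(names(sl))))
    return("names of values and seqlengths differ")
  if (length(object@binSize) != 1L || object@binSize < 1L)
    return("binSize must be a positive integer")
  for (chr in names(v)) {
    x <- v[[chr]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0))
      return(sprintf("values for %s must be non-negative and finite", chr))
    if (length(x) != ceiling(sl[[chr]] / object@binSize))
      return(sprintf("values for %s have wrong length for binSize", chr))
  }
  if (!object@normalization %in% TRACK_STATES)
    return("unknown normalization state")
  TRUE
})

#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors
#' @param binSize bin width in bp
#' @param seqlengths named chromosome lengths in bp
#' @param normalization normalization state, default \code{"raw"}
#' @param libSize total signal; defaults to \code{sum(unlist(values))}
#' @return a \linkS4class{SignalTrack}
#' @export
SignalTrack <- function(values, binSize, seqlengths, normalization = "raw",
                        libSize = sum(unlist(values, use.names = FALSE))) {
  new("SignalTrack", values = as.list(values), binSize = as.integer(binSize),
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)),
      libSize = as.numeric(libSize), normalization = normalization)
}

#' @rdname binSize
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname trackValues
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname normalizationState
#' @export
setMethod("normalizationState", "SignalTrack", function(x) x@normalization)

#' @rdname libSize
#' @export
setMethod("libSize", "SignalTrack", function(x) x@libSize)

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@values), "chromosome(s),",
      "bin", object@binSize, "bp,",
      sum(lengths(object@values)), "bins,",
      "state:", object@normalization, "\n")
})

#' Region-by-sample count container
#'
#' A \code{RangedSummarizedExperiment} holding integer read counts over a set
#' of regions (islands, enhancers or genes-as-regions) for multiple samples,
#' with sample metadata (genotype, age, cell fraction, replicate) in
#' \code{colData} and per-sample size factors.
#'
#' @export
setClass("RegionCounts", contains = "RangedSummarizedExperiment")

setValidity("RegionCounts", function(object) {
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cnt) || any(cnt < 0)) return("counts must be non-negative")
  if ("sizeFactor" %in% colnames(colData(object))) {
    sf <- colData(object)$sizeFactor
    if (anyNA(sf) || any(sf <= 0)) return("size factors must be positive")
  }
  TRUE
})

#' Construct a RegionCounts object
#'
#' @param regions GRanges of regions (rows)
#' @param counts regions x samples matrix of non-negative counts
#' @param sampleData data.frame of per-sample metadata (one row per column of
#'   \code{counts})
#' @param sizeFactors optional positive per-sample size factors
#' @return a \linkS4class{RegionCounts}
#' @export
RegionCounts <- function(regions, counts, sampleData = NULL,
                         sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = colnames(counts))
  cd <- DataFrame(sampleData)
  if (!is.null(sizeFactors)) cd$sizeFactor <- as.numeric(sizeFactors)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = regions, colData = cd)
  new("RegionCounts", se)
}

#' @rdname RegionCounts
#' @param object a RegionCounts object
#' @export
setMethod("sizeFactors", "RegionCounts", function(object) {
  if (!"sizeFactor" %in% colnames(colData(object))) return(NULL)
  setNames(colData(object)$sizeFactor, colnames(object))
})

#' Cell-type-specific enhancer catalogue
#'
#' Intervals labelled \code{neuronal} or \code{glial}, derived from a
#' sorted-nuclei (NeuN+ vs NeuN-) differential H3K27ac contrast. The two label
#' sets are disjoint.
#'
#' @slot regions GRanges with a \code{label} metadata column
#' @slot provenance list recording the contrast and threshold used
#' @export
setClass("EnhancerCatalogue", representation(
  regions = "GRanges", provenance = "list"))

setValidity("EnhancerCatalogue", function(object) {
  lab <- mcols(object@regions)$label
  if (length(object@regions) > 0 &&
      (is.null(lab) || !all(lab %in% c("neuronal", "glial"))))
    return("regions must carry a label column with values neuronal/glial")
  neu <- object@regions[lab == "neuronal"]
  gli <- object@regions[lab == "glial"]
  if (length(neu) && length(gli) &&
      length(findOverlaps(neu, gli)) > 0)
    return("neuronal and glial region sets must be disjoint")
  TRUE
})

#' Construct an EnhancerCatalogue
#' @param regions GRanges with a \code{label} metadata column
#'   (\code{neuronal}/\code{glial})
#' @param provenance list describing the contrast and threshold
#' @return an \linkS4class{EnhancerCatalogue}
#' @export
EnhancerCatalogue <- function(regions, provenance = list()) {
  new("EnhancerCatalogue", regions = regions, provenance = provenance)
}

#' @rdname catalogueRegions
#' @export
setMethod("catalogueRegions", "EnhancerCatalogue", function(x) x@regions)

setMethod("show", "EnhancerCatalogue", function(object) {
  lab <- mcols(object@regions)$label
  cat("EnhancerCatalogue:", sum(lab == "neuronal"), "neuronal,",
      sum(lab == "glial"), "glial regions\n")
})

setMethod("length", "EnhancerCatalogue", function(x) length(x@regions))

#' Restriction-fragment map
#'
#' Fragments tiling each chromosome, delimited by first-cutter sites (the 4-bp
#' site is assigned to the downstream fragment, i.e. each internal fragment
#' starts at a site start). Fragments are annotated with second-cutter
#' presence; fragments with no internal second-cutter site are \emph{blind}.
#'
#' @slot fragments GRanges with metadata columns \code{nSecond},
#'   \code{firstSecondOffset} (bp from fragment start to the first
#'   second-cutter site start; NA if blind) and \code{blind}
#' @slot firstSite first-cutter recognition sequence
#' @slot secondSite second-cutter recognition sequence
#' @export
setClass("FragmentMap", representation(
  fragments = "GRanges", firstSite = "character", secondSite = "character"))

setValidity("FragmentMap", function(object) {
  fr <- object@fragments
  for (chr in unique(as.character(seqnames(fr)))) {
    f <- fr[seqnames(fr) == chr]
    f <- f[order(start(f))]
    if (length(f) > 1 && any(start(f)[-1] != end(f)[-length(f)] + 1L))
      return(sprintf("fragments do not tile chromosome %s", chr))
  }
  TRUE
})

#' @rdname fragments
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)

setMethod("show", "FragmentMap", function(object) {
  cat("FragmentMap:", length(object@fragments), "fragments (",
      object@firstSite, "/", object@secondSite, "),",
      sum(mcols(object@fragments)$blind), "blind\n")
})

setMethod("length", "FragmentMap", function(x) length(x@fragments))

#' Per-fragment 4C-seq profile for one bait
#'
#' @slot bait GRanges of the bait fragment
#' @slot baitIndex index of the bait fragment within \code{fragments}
#' @slot fragments GRanges of scored restriction fragments (fragment order)
#' @slot counts raw per-fragment counts
#' @slot score normalized per-fragment scores (NA at excluded fragments)
#' @slot excluded indices of bait-proximal fragments excluded from scoring
#' @slot sampleInfo list of sample metadata (condition, replicate, sex...)
#' @export
setClass("FourCProfile", representation(
  bait = "GRanges", baitIndex = "integer", fragments = "GRanges",
  counts = "numeric", score = "numeric", excluded = "integer",
  sampleInfo = "list"))

setValidity("FourCProfile", function(object) {
  n <- length(object@fragments)
  if (length(object@counts) != n || length(object@score) != n)
    return("counts/score length must match fragments")
  if (any(object@counts < 0, na.rm = TRUE)) return("counts must be >= 0")
  if (length(object@excluded) &&
      (min(object@excluded) < 1 || max(object@excluded) > n))
    return("excluded indices out of range")
  if (length(object@excluded) && any(!is.na(object@score[object@excluded])))
    return("excluded fragments must carry no score")
  TRUE
})

#' Construct a FourCProfile
#' @param fragments GRanges of restriction fragments, in genomic order
#' @param counts per-fragment raw counts
#' @param baitIndex index of the bait fragment
#' @param excluded indices excluded from scoring (defaults to the bait
#'   fragment +/- \code{baitFlank} fragments: self-ligation and undigested
#'   artefacts)
#' @param baitFlank number of fragments on each side of the bait to exclude
#' @param score normalized scores; defaults to the raw counts with excluded
#'   set to NA
#' @param sampleInfo list of sample metadata
#' @return a \linkS4class{FourCProfile}
#' @export
FourCProfile <- function(fragments, counts, baitIndex, excluded = NULL,
                         baitFlank = 2L, score = NULL, sampleInfo = list()) {
  n <- length(fragments)
  baitIndex <- as.integer(baitIndex)
  if (baitIndex < 1L || baitIndex > n) stop("bait index out of range")
  if (is.null(excluded))
    excluded <- seq(max(1L, baitIndex - baitFlank),
                    min(n, baitIndex + baitFlank))
  excluded <- as.integer(excluded)
  if (is.null(score)) {
    score <- as.numeric(counts)
    score[excluded] <- NA_real_
  }
  new("FourCProfile", bait = fragments[baitIndex], baitIndex = baitIndex,
      fragments = fragments, counts = as.numeric(counts), score = score,
      excluded = excluded, sampleInfo = sampleInfo)
}

setMethod("show", "FourCProfile", function(object) {
  cat("FourCProfile: bait fragment", object@baitIndex, "of",
      length(object@fragments), "fragments;",
      length(object@excluded), "excluded\n")
})

#' Bead chain describing a modelled locus
#'
#' @slot nBeads number of beads (>= 10)
#' @slot fragmentsPerBead restriction fragments represented by each bead
#' @slot bpPerBead genomic span per bead in bp
#' @slot baitBeads bead indices of the 4C baits
#' @export
setClass("BeadChain", representation(
  nBeads = "integer", fragmentsPerBead = "integer",
  bpPerBead = "numeric", baitBeads = "integer"))

setValidity("BeadChain", function(object) {
  if (object@nBeads < 10L) return("nBeads must be >= 10")
  if (length(object@baitBeads) &&
      (min(object@baitBeads) < 1L || max(object@baitBeads) > object@nBeads))
    return("bait bead indices out of range")
  if (anyDuplicated(object@baitBeads)) return("duplicate bait beads")
  TRUE
})

#' Construct a BeadChain
#' @param nBeads number of beads
#' @param baitBeads bead indices of the baits
#' @param fragmentsPerBead fragments per bead (default 25)
#' @param bpPerBead genomic bp per bead (default 10000)
#' @return a \linkS4class{BeadChain}
#' @export
BeadChain <- function(nBeads, baitBeads = integer(0), fragmentsPerBead = 25L,
                      bpPerBead = 1e4) {
  new("BeadChain", nBeads = as.integer(nBeads),
      fragmentsPerBead = as.integer(fragmentsPerBead),
      bpPerBead = as.numeric(bpPerBead), baitBeads = as.integer(baitBeads))
}

#' Fitted 3D bead model
#'
#' @slot coords beads x 3 coordinate matrix (arbitrary model units)
#' @slot objective final objective value of the restrained optimization
#' @slot seed RNG seed used for the restarts
#' @slot restart index of the winning restart
#' @slot chain the \linkS4class{BeadChain} the model is defined on
#' @export
setClass("BeadModel", representation(
  coords = "matrix", objective = "numeric", seed = "integer",
  restart = "integer", chain = "BeadChain"))

setValidity("BeadModel", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (nrow(object@coords) != object@chain@nBeads)
    return("coords rows must equal chain beads")
  TRUE
})

#' @rdname beadCoords
#' @export
setMethod("beadCoords", "BeadModel", function(x) x@coords)

setMethod("show", "BeadModel", function(object) {
  cat("BeadModel:", nrow(object@coords), "beads, objective",
      format(object@objective, digits = 4), "(restart", object@restart, ")\n")
})

#' Virtual Hi-C distance matrix
#'
#' All-pairs Euclidean bead distances derived from a fitted model: symmetric,
#' zero diagonal, triangle inequality by construction.
#'
#' @slot distances symmetric numeric matrix
#' @export
setClass("VirtualHiC", representation(distances = "matrix"))

setValidity("VirtualHiC", function(object) {
  d <- object@distances
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (any(d < 0)) return("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) return("matrix must be symmetric")
  TRUE
})

#' Construct a VirtualHiC from a distance matrix
#' @param distances symmetric non-negative matrix with zero diagonal
#' @return a \linkS4class{VirtualHiC}
#' @export
VirtualHiC <- function(distances) {
  new("VirtualHiC", distances = unname(as.matrix(distances)))
}

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "VirtualHiC", function(x) x@distances)

setMethod("show", "VirtualHiC", function(object) {
  cat("VirtualHiC:", nrow(object@distances), "x", ncol(object@distances),
      "distance matrix\n")
})

setMethod("dim", "VirtualHiC", function(x) dim(x@distances))

#' Multi-scale insulation profile
#'
#' Per-bead insulation values across window sizes (z-scored per window size),
#' the scale-averaged aggregate profile, and boundary calls (local minima of
#' the aggregate with sufficient prominence).
#'
#' @slot perBin window-size x position matrix of z-scored insulation (NA where
#'   the full window does not fit)
#' @slot aggregate scale-averaged profile (NA outside the common support)
#' @slot boundaries bead indices of detected boundaries
#' @slot bRange integer window sizes used (beads)
#' @slot bpPerBead genomic span per bead
#' @export
setClass("InsulationProfile", representation(
  perBin = "matrix", aggregate = "numeric", boundaries = "integer",
  bRange = "integer", bpPerBead = "numeric"))

#' @rdname aggregateInsulation
#' @export
setMethod("aggregateInsulation", "InsulationProfile", function(x) x@aggregate)

#' @rdname insulationBoundaries
#' @export
setMethod("insulationBoundaries", "InsulationProfile", function(x) x@boundaries)

setMethod("show", "InsulationProfile", function(object) {
  cat("InsulationProfile:", length(object@aggregate), "positions, windows",
      min(object@bRange), "-", max(object@bRange), "beads;",
      length(object@boundaries), "boundary call(s)\n")
})

#' Simulation configuration with planted ground truth structure
#'
#' Encodes the study conditions emulated by the synthetic-data generator: a
#' small two-chromosome genome, cell-type structured enhancers, genotype and
#' age effects of fixed sign structure (neuronal enhancers depleted, glial
#' enriched under the disease genotype, concordant with age, with larger
#' amplitude at the later age), negative-binomial noise, and the neuronal
#' (NeuN+) fraction of bulk tissue.
#'
#' @slot seed integer RNG seed
#' @slot genome named numeric chromosome lengths in bp
#' @slot binSize track bin width in bp
#' @slot nGenes number of genes
#' @slot enhancerPlan data.frame with columns class, n, width
#' @slot effectPlan data.frame with columns class, genotypeAge1, genotypeAge2,
#'   age (log2 effect sizes)
#' @slot dispersion negative-binomial dispersion of ChIP counts
#' @slot libRange relative library-size range (min, max)
#' @slot mixture NeuN+ fraction of bulk tissue, identical across genotypes
#' @slot backgroundMean expected background reads per bin
#' @slot enhancerFold fold-enrichment of marked enhancer/gene-body bins
#' @slot rnaCoupling coupling weight between enhancer and mRNA log2 effects
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", genome = "numeric", binSize = "integer",
  nGenes = "integer", enhancerPlan = "data.frame", effectPlan = "data.frame",
  dispersion = "numeric", libRange = "numeric", mixture = "numeric",
  backgroundMean = "numeric", enhancerFold = "numeric",
  rnaCoupling = "numeric"))

setValidity("SimulationConfig", function(object) {
  ep <- object@effectPlan
  need <- c("class", "genotypeAge1", "genotypeAge2", "age")
  if (!all(need %in% names(ep))) return("effectPlan missing columns")
  neu <- ep[ep$class == "neuronal", ]
  gli <- ep[ep$class == "glial", ]
  if (nrow(neu) && any(c(neu$genotypeAge1, neu$genotypeAge2) > 0))
    return("neuronal genotype effects must be <= 0")
  if (nrow(gli) && any(c(gli$genotypeAge1, gli$genotypeAge2) < 0))
    return("glial genotype effects must be >= 0")
  if (any(abs(ep$genotypeAge2) < abs(ep$genotypeAge1)))
    return("|genotype effect at age 2| must be >= |at age 1| (progressive)")
  if (object@mixture <= 0 || object@mixture >= 1)
    return("mixture must be in (0, 1)")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@genome), "chromosome(s),",
      sum(object@genome) / 1e6, "Mb,", object@nGenes, "genes,",
      sum(object@enhancerPlan$n), "enhancers, NeuN+ mixture",
      object@mixture, "\n")
})
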