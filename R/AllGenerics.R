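#' @import methods
#' @importFrom stats dpois ppois dbinom rnbinom rpois runif rnorm rlnorm
#'   p.adjust kmeans kruskal.test t.test cor cor.test lm coef sd var median
#'   quantile isoreg hclust dist optim setNames complete.cases pt
#'   pairwise.wilcox.test approx aggregate
#' @importFrom utils head tail read.table write.table
NULL

#' Bin size of a signal track
#' @param x object
#' @return integer bin width in bp
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Per-chromosome value vectors of a signal track
#' @param x object
#' @return named list of numeric vectors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Normalization state of a signal track
#' @param x object
#' @return character scalar
#' @export
setGeneric("normalizationState", function(x) standardGeneric("normalizationState"))

#' Total signal (library size proxy) of a track
#' @param x object
#' @return numeric scalar
#' @export
setGeneric("libSize", function(x) standardGeneric("libSize"))

#' Labelled regions of an enhancer catalogue
#' @param x object
#' @return GRanges with a \code{label} metadata column
#' @export
setGeneric("catalogueRegions", function(x) standardGeneric("catalogueRegions"))

#' Restriction fragments of a fragment map
#' @param x object
#' @return GRanges of fragments with validity annotations
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Bead coordinates of a 3D chromatin model
#' @param x object
#' @return numeric matrix (beads x 3)
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))

#' All-pairs distance matrix
#' @param x object
#' @return symmetric numeric matrix with zero diagonal
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' Aggregate (scale-averaged) insulation profile
#' @param x object
#' @return numeric vector, NA where the largest window does not fit
#' @export
setGeneric("aggregateInsulation", function(x) standardGeneric("aggregateInsulation"))

#' Detected insulation boundaries
#' @param x object
#' @return integer vector of bead positions
#' @export
setGeneric("insulationBoundaries", function(x) standardGeneric("insulationBoundaries"))
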