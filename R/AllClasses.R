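#' @import methods
#' @importFrom stats quantile rnorm runif rlnorm sd median rank pnorm
#'   qnorm setNames aggregate
#' @importFrom utils head read.csv write.csv read.delim packageVersion
NULL

#' ChannelStack: named co-registered 2D intensity channels
#'
#' Container for a multi-channel 2D fluorescence field: a named list of
#' equally sized numeric matrices (grey levels, `[row, col]` indexing) plus
#' the physical pixel size in micrometres per pixel. This is the raw input
#' of the whole pipeline; channels are typically a nuclear stain (DAPI), an
#' epithelial/cancer marker (pan-cytokeratin), a stromal matrix protein
#' (fibronectin) and one or more analysis markers.
#'
#' @slot channels Named list of numeric matrices, all with identical
#'   dimensions.
#' @slot pixelSize Positive numeric scalar, micrometres per pixel.
#' @seealso [channelStack()], [getChannel()], [generateTissue()]
#' @export
setClass("ChannelStack",
  representation(channels = "list", pixelSize = "numeric"))

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a numeric matrix")
  d <- dim(ch[[1]])
  if (!all(vapply(ch, function(m) identical(dim(m), d), logical(1))))
    return("all channels must share the same dimensions")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/px)")
  TRUE
})

#' Construct a ChannelStack
#'
#' @param channels Named list of numeric matrices (grey levels), identical
#'   dimensions.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return A [ChannelStack-class] object.
#' @examples
#' cs <- channelStack(list(DAPI = matrix(0, 8, 8)), pixel_size_um = 0.5)
#' channelNames(cs)
#' @export
channelStack <- function(channels, pixel_size_um) {
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  new("ChannelStack", channels = channels, pixelSize = as.numeric(pixel_size_um))
}

#' @describeIn channelStack Channel names.
#' @param x A `ChannelStack`.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn channelStack Extract one channel as a matrix.
#' @param name Channel name.
#' @export
getChannel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop("channel '", name, "' not present (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
}

#' @describeIn channelStack Pixel size in micrometres per pixel.
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("dim", "ChannelStack", function(x) dim(x@channels[[1]]))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object)
  cat("ChannelStack:", d[1], "x", d[2], "px @", object@pixelSize, "um/px\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' FittedDistribution: a fitted positive continuous intensity model
#'
#' One candidate family (log-normal, gamma, Weibull or exponential) fitted
#' by maximum likelihood to a sample of per-cell intensities, scored by the
#' least-squares error between its density and the normalized intensity
#' histogram. Carries the CDF/quantile contract used for percentile-
#' preserving threshold propagation.
#'
#' @slot family Family name: one of `"lnorm"`, `"gamma"`, `"weibull"`,
#'   `"exp"`.
#' @slot estimate Named numeric vector of fitted parameters.
#' @slot sse Least-squares error of fitted density vs normalized histogram.
#' @slot histBinWidth Histogram bin width used for the SSE score.
#' @slot nSamples Number of (positive) samples used in the fit.
#' @slot nExcluded Number of non-positive values excluded before fitting.
#' @seealso [fitBestDistribution()], [thresholdToPercentile()],
#'   [percentileToThreshold()]
#' @export
setClass("FittedDistribution",
  representation(family = "character", estimate = "numeric", sse = "numeric",
                 histBinWidth = "numeric", nSamples = "integer",
                 nExcluded = "integer"))

setValidity("FittedDistribution", function(object) {
  if (!object@family %in% c("lnorm", "gamma", "weibull", "exp"))
    return("unknown family")
  if (object@sse < 0) return("sse must be non-negative")
  if (object@histBinWidth <= 0) return("histBinWidth must be positive")
  TRUE
})

setMethod("show", "FittedDistribution", function(object) {
  cat("FittedDistribution:", object@family, "(",
      paste(names(object@estimate), signif(object@estimate, 4),
            sep = "=", collapse = ", "),
      ") sse =", signif(object@sse, 4),
      "n =", object@nSamples, "\n")
})

#' ThresholdMap: an expert threshold propagated across images
#'
#' Records the reference image and expert-chosen threshold, the percentile
#' that threshold occupies under the reference image's fitted intensity
#' distribution, and the translated threshold (that percentile's quantile
#' under each image's own fit) for every image in the batch.
#'
#' @slot referenceImage Reference image id.
#' @slot marker Measurement column the thresholds apply to (e.g.
#'   `"Cell: MARKER max"`).
#' @slot referenceThreshold Expert threshold in the reference image, grey
#'   levels.
#' @slot percentile CDF of the reference threshold under the reference fit.
#' @slot thresholds Named numeric vector: translated threshold per image.
#' @slot fits Named list of [FittedDistribution-class], one per image.
#' @seealso [propagateThresholds()], [classifyByThreshold()]
#' @export
setClass("ThresholdMap",
  representation(referenceImage = "character", marker = "character",
                 referenceThreshold = "numeric", percentile = "numeric",
                 thresholds = "numeric", fits = "list"))

setValidity("ThresholdMap", function(object) {
  if (object@percentile <= 0 || object@percentile >= 1)
    return("percentile must lie in (0, 1)")
  if (!object@referenceImage %in% names(object@thresholds))
    return("reference image missing from thresholds")
  if (!identical(names(object@thresholds), names(object@fits)))
    return("thresholds and fits must be named identically")
  TRUE
})

setMethod("show", "ThresholdMap", function(object) {
  cat("ThresholdMap for '", object@marker, "'\n", sep = "")
  cat("  reference:", object@referenceImage, "threshold =",
      signif(object@referenceThreshold, 6),
      "-> percentile", signif(object@percentile, 6), "\n")
  for (id in names(object@thresholds))
    cat("  ", id, ": ", signif(object@thresholds[[id]], 6), " (",
        object@fits[[id]]@family, ")\n", sep = "")
})

#' StromalModel: stromal mask, border and signed distance field
#'
#' The stromal compartment modeled from a matrix-protein channel: Gaussian
#' smoothing at `sigmaUm`, strict thresholding at `threshold`, the border
#' pixel set (mask pixels with at least one non-mask 4-neighbor; the image
#' edge does not count as border), and the per-pixel signed Euclidean
#' distance to the border in micrometres (negative inside the mask). When
#' the mask has no border, the distance map is entirely `+Inf`.
#'
#' @slot sigmaUm Gaussian smoothing sigma, micrometres.
#' @slot threshold Intensity threshold (grey levels) applied to the
#'   smoothed channel, strict `>`.
#' @slot pixelSize Micrometres per pixel.
#' @slot mask Logical matrix, `TRUE` = stromal.
#' @slot border Integer matrix, one row per border pixel, columns
#'   `row`, `col` (1-based).
#' @slot distanceMap Numeric matrix, signed distance in micrometres.
#' @seealso [buildStromalModel()], [signedDistance()]
#' @export
setClass("StromalModel",
  representation(sigmaUm = "numeric", threshold = "numeric",
                 pixelSize = "numeric", mask = "matrix", border = "matrix",
                 distanceMap = "matrix"))

setMethod("show", "StromalModel", function(object) {
  d <- dim(object@mask)
  cat("StromalModel:", d[1], "x", d[2], "px, sigma =", object@sigmaUm,
      "um, threshold =", signif(object@threshold, 6), "\n")
  cat("  stromal fraction:", signif(mean(object@mask), 4),
      "| border pixels:", nrow(object@border), "\n")
})

#' @describeIn buildStromalModel Logical stromal mask of a model.
#' @export
stromalMask <- function(model) model@mask

#' @describeIn buildStromalModel Border pixel coordinates (`row`, `col`,
#'   1-based) of a model.
#' @export
stromalBorder <- function(model) model@border

#' @describeIn buildStromalModel Per-pixel signed distance map in
#'   micrometres (negative inside stroma, `+Inf` when there is no border).
#' @export
distanceMap <- function(model) model@distanceMap

#' BinProfile: distance-binned marker intensity profile
#'
#' Summary of one cell population along signed distance to the stromal
#' border: per 10-um (by default) bin, the number of cells, the mean of
#' the chosen intensity column, the within-bin standard deviation, and the
#' bootstrap standard error of the bin mean. Bins are half-open
#' `[edge, edge + width)` and aligned so that 0 (the border) is an edge.
#'
#' @slot binEdges Ordered numeric vector of bin edges, micrometres.
#' @slot n Integer cells per bin.
#' @slot mean Per-bin mean intensity (`NA` for empty bins).
#' @slot sd Per-bin sample standard deviation (`NA` when `n < 2`).
#' @slot sem Per-bin bootstrap SEM (`NA` for empty bins).
#' @slot population Label of the profiled population.
#' @slot column Intensity column profiled.
#' @seealso [distanceProfile()], [profileDifference()], [plotProfile()]
#' @export
setClass("BinProfile",
  representation(binEdges = "numeric", n = "integer", mean = "numeric",
                 sd = "numeric", sem = "numeric", population = "character",
                 column = "character"))

setValidity("BinProfile", function(object) {
  k <- length(object@binEdges) - 1
  if (k < 1) return("need at least two bin edges")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    return("bin edges must be strictly increasing")
  if (length(object@n) != k || length(object@mean) != k ||
      length(object@sd) != k || length(object@sem) != k)
    return("n, mean, sd, sem must have one entry per bin")
  if (any(object@n < 0)) return("bin counts must be non-negative")
  TRUE
})

#' Construct a BinProfile from known per-bin summaries
#'
#' Mostly used internally by [distanceProfile()]; exported so profiles can
#' be built from externally computed summaries (e.g. known within-bin
#' standard deviations) and fed to [profileDifference()].
#'
#' @param bin_edges Ordered numeric bin edges (micrometres).
#' @param n Integer cells per bin.
#' @param mean,sd,sem Per-bin mean, standard deviation, SEM.
#' @param population,column Labels.
#' @return A [BinProfile-class].
#' @export
binProfile <- function(bin_edges, n, mean, sd = rep(NA_real_, length(n)),
                       sem = rep(NA_real_, length(n)),
                       population = "", column = "") {
  new("BinProfile", binEdges = as.numeric(bin_edges), n = as.integer(n),
      mean = as.numeric(mean), sd = as.numeric(sd), sem = as.numeric(sem),
      population = population, column = column)
}

setMethod("show", "BinProfile", function(object) {
  cat("BinProfile", if (nzchar(object@population))
        paste0("[", object@population, "]"), "on",
      if (nzchar(object@column)) object@column else "<column>", "\n")
  cat("  ", length(object@n), " bins over [", min(object@binEdges), ", ",
      max(object@binEdges), ") um, ", sum(object@n), " cells\n", sep = "")
})

#' Convert a BinProfile to a data.frame
#'
#' @param x A [BinProfile-class].
#' @param ... Ignored.
#' @return data.frame with columns `bin_left`, `bin_right`, `n`, `mean`,
#'   `sd`, `sem`.
#' @export
setMethod("as.data.frame", "BinProfile", function(x, ...) {
  k <- length(x@binEdges) - 1
  data.frame(bin_left = x@binEdges[seq_len(k)],
             bin_right = x@binEdges[seq_len(k) + 1],
             n = x@n, mean = x@mean, sd = x@sd, sem = x@sem)
})

#' ConfusionSummary: agreement between two label vectors
#'
#' Cross-tabulation of two classifications of the same cells (rows =
#' method A, columns = method B) plus the percent agreement,
#' `100 * trace / total`.
#'
#' @slot labels Shared label alphabet (sorted union).
#' @slot counts Integer count matrix.
#' @slot agreementPct Percent agreement in `[0, 100]`.
#' @seealso [agreement()]
#' @export
setClass("ConfusionSummary",
  representation(labels = "character", counts = "matrix",
                 agreementPct = "numeric"))

setMethod("show", "ConfusionSummary", function(object) {
  cat("ConfusionSummary (", sum(object@counts), " cells): agreement ",
      signif(object@agreementPct, 4), "%\n", sep = "")
  print(object@counts)
})
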