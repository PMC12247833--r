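# Percentile-preserving threshold calibration across images.
#
# Expert-chosen intensity thresholds do not transfer between images whose
# staining intensity differs. The calibration strategy is: model each
# image's per-cell intensity sample with the best-fitting positive
# continuous distribution, read off the percentile the expert threshold
# occupies under the reference image's fit, and invert that percentile
# under every other image's fit.

.familyFuns <- list(
  lnorm   = list(d = stats::dlnorm,  p = stats::plnorm,  q = stats::qlnorm),
  gamma   = list(d = stats::dgamma,  p = stats::pgamma,  q = stats::qgamma),
  weibull = list(d = stats::dweibull, p = stats::pweibull, q = stats::qweibull),
  exp     = list(d = stats::dexp,    p = stats::pexp,    q = stats::qexp)
)

.evalFamily <- function(which, family, x, estimate) {
  f <- .familyFuns[[family]][[which]]
  do.call(f, c(list(x), as.list(estimate)))
}

# Freedman-Diaconis bin width with fallbacks for degenerate IQR.
.fdBinWidth <- function(x) {
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / 30
  if (!is.finite(bw) || bw <= 0) bw <- 1
  bw
}

#' Fit the best positive continuous distribution to an intensity sample
#'
#' Fits each candidate family (default log-normal, gamma, Weibull,
#' exponential) by maximum likelihood, scores each fit by the sum of
#' squared differences between its density and the normalized intensity
#' histogram at the bin centers, and returns the family minimizing that
#' least-squares error (ties broken by candidate order). Fluorescence
#' intensity histograms are typically right-skewed and "elbow"-shaped, and
#' the log-normal family is usually selected.
#'
#' Non-positive values are excluded before fitting (the candidate families
#' have positive support); the number excluded is recorded in the result
#' and reported with a message.
#'
#' @param values Numeric intensity sample; at least 50 positive values.
#' @param candidates Character vector of families to try, a subset of
#'   `c("lnorm", "gamma", "weibull", "exp")`, in tie-break order.
#' @param hist_bin_width Histogram bin width for the SSE score; default is
#'   the Freedman-Diaconis width.
#' @return A [FittedDistribution-class].
#' @examples
#' set.seed(1)
#' fit <- fitBestDistribution(rlnorm(5000, 3, 0.5))
#' fit@family   # "lnorm"
#' @export
fitBestDistribution <- function(values,
                                candidates = c("lnorm", "gamma", "weibull", "exp"),
                                hist_bin_width = NULL) {
  if (!all(candidates %in% names(.familyFuns)))
    stop("unknown candidate families: ",
         paste(setdiff(candidates, names(.familyFuns)), collapse = ", "))
  values <- values[is.finite(values)]
  n_excluded <- sum(values <= 0)
  x <- values[values > 0]
  if (n_excluded > 0)
    message("fitBestDistribution: excluded ", n_excluded,
            " non-positive values from fitting")
  if (length(x) < 50)
    stop("need at least 50 positive samples, got ", length(x))
  if (diff(range(x)) < .Machine$double.eps * max(abs(x)))
    stop("degenerate sample: all values are (numerically) equal")

  bw <- if (is.null(hist_bin_width)) .fdBinWidth(x) else hist_bin_width
  if (bw <= 0) stop("hist_bin_width must be positive")
  breaks <- seq(floor(min(x) / bw) * bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)

  best <- NULL
  for (fam in candidates) {
    fit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, fam, method = "mle")),
      error = function(e) NULL)
    if (is.null(fit)) next
    dens <- .evalFamily("d", fam, h$mids, fit$estimate)
    sse <- sum((h$density - dens)^2)
    if (!is.finite(sse)) next
    if (is.null(best) || sse < best$sse)
      best <- list(family = fam, estimate = fit$estimate, sse = sse)
  }
  if (is.null(best)) stop("no candidate family could be fitted")
  new("FittedDistribution", family = best$family,
      estimate = best$estimate, sse = best$sse, histBinWidth = bw,
      nSamples = length(x), nExcluded = as.integer(n_excluded))
}

#' Map an intensity threshold to its percentile under a fitted distribution
#'
#' @param fit A [FittedDistribution-class].
#' @param threshold Intensity threshold, grey levels; must be positive
#'   (all supported families have positive support).
#' @return The fitted CDF at `threshold`, in (0, 1).
#' @seealso [percentileToThreshold()]
#' @export
thresholdToPercentile <- function(fit, threshold) {
  stopifnot(is(fit, "FittedDistribution"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive for positive-support families")
  .evalFamily("p", fit@family, threshold, fit@estimate)
}

#' Map a percentile back to an intensity threshold
#'
#' Inverse of [thresholdToPercentile()]: the fitted quantile.
#'
#' @param fit A [FittedDistribution-class].
#' @param p Percentile in (0, 1), exclusive.
#' @return The fitted quantile at `p`, grey levels.
#' @export
percentileToThreshold <- function(fit, p) {
  stopifnot(is(fit, "FittedDistribution"))
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1)")
  .evalFamily("q", fit@family, p, fit@estimate)
}

#' Propagate an expert threshold across images by percentile preservation
#'
#' Fits each image's intensity column, maps the expert threshold chosen in
#' the reference image to its percentile under the reference fit, and
#' translates it to every image as that percentile's quantile under the
#' image's own fit. A consistent fraction of cells (1 - percentile) is
#' thereby classified positive in each image even when absolute staining
#' intensity shifts between images.
#'
#' @param tables Either a named list of cell tables (one per image) or a
#'   single cell table with an `image_id` column.
#' @param marker Name of the intensity column to calibrate (e.g.
#'   `"Cell: MARKER max"`).
#' @param reference_image_id Id (list name or `image_id` value) of the
#'   reference image.
#' @param reference_threshold Expert threshold in the reference image.
#' @param candidates,hist_bin_width Passed to [fitBestDistribution()].
#' @return A [ThresholdMap-class].
#' @export
propagateThresholds <- function(tables, marker, reference_image_id,
                                reference_threshold,
                                candidates = c("lnorm", "gamma", "weibull", "exp"),
                                hist_bin_width = NULL) {
  if (is.data.frame(tables)) {
    if (!"image_id" %in% names(tables))
      stop("a single table must carry an 'image_id' column")
    tables <- split(tables, tables$image_id)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (one entry per image)")
  for (id in names(tables))
    if (!marker %in% names(tables[[id]]))
      stop("marker column '", marker, "' missing from image '", id, "'")
  if (!reference_image_id %in% names(tables))
    stop("reference image '", reference_image_id, "' not among tables")

  fits <- list()
  for (id in names(tables)) {
    fits[[id]] <- tryCatch(
      fitBestDistribution(tables[[id]][[marker]], candidates = candidates,
                          hist_bin_width = hist_bin_width),
      error = function(e)
        stop("distribution fit failed for image '", id, "': ",
             conditionMessage(e), call. = FALSE))
  }
  p <- thresholdToPercentile(fits[[reference_image_id]], reference_threshold)
  thresholds <- vapply(fits, percentileToThreshold, numeric(1), p = p)
  new("ThresholdMap", referenceImage = reference_image_id, marker = marker,
      referenceThreshold = as.numeric(reference_threshold),
      percentile = as.numeric(p), thresholds = thresholds, fits = fits)
}

#' Serialize / read a ThresholdMap as JSON
#'
#' @param map A [ThresholdMap-class].
#' @param path Output (or input) JSON file path.
#' @return `writeThresholdMap` returns `path` invisibly;
#'   `readThresholdMap` returns a [ThresholdMap-class].
#' @export
writeThresholdMap <- function(map, path) {
  obj <- list(
    reference_image = map@referenceImage,
    marker = map@marker,
    reference_threshold = map@referenceThreshold,
    percentile = map@percentile,
    images = lapply(names(map@thresholds), function(id) {
      f <- map@fits[[id]]
      list(image_id = id, translated_threshold = map@thresholds[[id]],
           family = f@family, estimate = as.list(f@estimate), sse = f@sse,
           hist_bin_width = f@histBinWidth, n_samples = f@nSamples,
           n_excluded = f@nExcluded)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholdMap
#' @export
readThresholdMap <- function(path) {
  obj <- jsonlite::read_json(path)
  fits <- list(); thr <- numeric(0)
  for (im in obj$images) {
    fits[[im$image_id]] <- new("FittedDistribution", family = im$family,
      estimate = unlist(im$estimate), sse = im$sse,
      histBinWidth = im$hist_bin_width, nSamples = as.integer(im$n_samples),
      nExcluded = as.integer(im$n_excluded))
    thr[[im$image_id]] <- im$translated_threshold
  }
  new("ThresholdMap", referenceImage = obj$reference_image,
      marker = obj$marker,
      referenceThreshold = obj$reference_threshold,
      percentile = obj$percentile, thresholds = thr, fits = fits)
}
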