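# Stromal region modeling and signed distances to its border.

# Border pixels of a logical mask: mask pixels with at least one non-mask
# 4-neighbor. Out-of-image neighbors are treated as mask, so the image
# edge never counts as stromal border (avoids edge artifacts in distance
# profiles).
.borderPixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  up    <- pad[1:nr,       2:(nc + 1)]
  down  <- pad[3:(nr + 2), 2:(nc + 1)]
  left  <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  border <- mask & !(up & down & left & right)
  which(border, arr.ind = TRUE)
}

#' Model the stromal region from a matrix-protein channel
#'
#' Smooths the channel with a Gaussian kernel (`sigma_um` converted to
#' pixels; 0 means no smoothing), thresholds the smoothed image with a
#' strict `>` comparison to obtain the stromal mask, extracts the border
#' (mask pixels with a non-mask 4-neighbor; the image edge is not border),
#' and derives the per-pixel signed Euclidean distance to the border in
#' micrometres, negative inside the mask. Distances use the exact
#' Euclidean metric between pixel centers. If the mask has no border
#' (empty or full-frame mask) the distance map is entirely `+Inf`.
#'
#' @param fn_channel 2D numeric matrix, matrix-protein (e.g. fibronectin)
#'   intensities in grey levels.
#' @param sigma_um Gaussian smoothing sigma in micrometres, `>= 0`.
#' @param threshold Intensity threshold in grey levels (applied to the
#'   smoothed image, strict `>`).
#' @param pixel_size_um Micrometres per pixel.
#' @param min_area_um2 Optional minimum stromal component area; connected
#'   mask components smaller than this are dropped (default 0, keep all).
#' @return A [StromalModel-class].
#' @examples
#' fn <- matrix(0, 32, 32); fn[, 1:16] <- 100
#' m <- buildStromalModel(fn, sigma_um = 0, threshold = 50, pixel_size_um = 1)
#' mean(stromalMask(m))  # 0.5
#' @export
buildStromalModel <- function(fn_channel, sigma_um, threshold, pixel_size_um,
                              min_area_um2 = 0) {
  stopIfNot2D(fn_channel, "fn_channel")
  if (sigma_um < 0) stop("sigma_um must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  sm <- gaussianSmooth(fn_channel, sigma_um / pixel_size_um)
  mask <- sm > threshold
  if (min_area_um2 > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    lab <- as.matrix(EBImage::imageData(lab))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * pixel_size_um^2 >= min_area_um2)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  border <- .borderPixels(mask)
  if (nrow(border) == 0) {
    dmap <- matrix(Inf, nrow(mask), ncol(mask))
  } else {
    bmask <- matrix(0, nrow(mask), ncol(mask))
    bmask[border] <- 1
    # distance of every pixel to the nearest border pixel center (exact
    # Euclidean distance transform); border pixels themselves get 0.
    d <- as.matrix(EBImage::imageData(EBImage::distmap(1 - bmask)))
    dmap <- d * ifelse(mask, -1, 1) * pixel_size_um
  }
  new("StromalModel", sigmaUm = as.numeric(sigma_um),
      threshold = as.numeric(threshold), pixelSize = as.numeric(pixel_size_um),
      mask = mask, border = border, distanceMap = dmap)
}

#' Signed Euclidean distance from points to the stromal border
#'
#' For each query point (typically a nuclear centroid, in micrometres),
#' the magnitude is the exact minimum Euclidean distance to any border
#' pixel center, and the sign is negative if and only if the point's
#' containing pixel lies inside the stromal mask. Points on border pixels
#' therefore have magnitudes of at most half a pixel diagonal.
#'
#' @param model A [StromalModel-class] with a non-empty border.
#' @param points_um Two-column numeric matrix or data.frame of `(x, y)`
#'   positions in micrometres (x along columns, y along rows, both
#'   measured from the first pixel center).
#' @return Numeric vector of signed distances in micrometres.
#' @export
signedDistance <- function(model, points_um) {
  stopifnot(is(model, "StromalModel"))
  if (nrow(model@border) == 0)
    stop("stromal border is empty (mask is empty or covers the full frame)")
  pts <- as.matrix(points_um)
  if (ncol(pts) != 2) stop("points_um must have two columns (x, y)")
  ps <- model@pixelSize
  # border pixel centers in um (0-based pixel grid)
  bx <- (model@border[, "col"] - 1) * ps
  by <- (model@border[, "row"] - 1) * ps
  n <- nrow(pts)
  mag <- numeric(n)
  chunk <- max(1L, floor(4e6 / length(bx)))
  for (s in seq(1, n, by = chunk)) {
    i <- s:min(s + chunk - 1, n)
    dx <- outer(pts[i, 1], bx, "-")
    dy <- outer(pts[i, 2], by, "-")
    d2 <- dx * dx + dy * dy
    mag[i] <- sqrt(d2[cbind(seq_along(i), max.col(-d2, ties.method = "first"))])
  }
  px <- umToPx(pts[, 1], pts[, 2], ps, dim(model@mask))
  inside <- model@mask[px]
  mag * ifelse(inside, -1, 1)
}

#' Write the stromal mask as an 8-bit TIFF
#'
#' @param model A [StromalModel-class].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
writeStromalMask <- function(model, path) {
  tiff::writeTIFF(model@mask * 1, path, bits.per.sample = 8)
  invisible(path)
}

#' Write the stromal border as GeoJSON polygons
#'
#' Traces the oriented contours of the stromal mask components and writes
#' them as a GeoJSON `MultiPolygon`-style feature collection with
#' coordinates in micrometres.
#'
#' @param model A [StromalModel-class].
#' @param path Output GeoJSON path.
#' @return `path`, invisibly.
#' @export
writeBorderGeoJSON <- function(model, path) {
  lab <- EBImage::bwlabel(model@mask * 1)
  oc <- EBImage::ocontour(lab)
  ps <- model@pixelSize
  feats <- lapply(oc, function(xy) {
    # ocontour works in EBImage's (x, y) = (row, col) order on our matrix;
    # swap to x = col, y = row and close the ring.
    ring <- cbind((xy[, 2]) * ps, (xy[, 1]) * ps)
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature", properties = list(role = "stromal_border"),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
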