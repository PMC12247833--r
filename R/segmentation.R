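# Per-cell nuclear and whole-cell label geometry.
#
# Nuclei label images normally come from an external segmenter (the
# pipeline treats segmentation as an exchangeable input); a built-in
# smoothed-threshold-watershed blob segmenter covers synthetic images.
# Whole-cell masks are obtained by a radial expansion of each nucleus,
# partitioned between neighbors by nearest-nucleus assignment.

.checkLabelImage <- function(labels) {
  if (!is.matrix(labels)) stop("label image must be a matrix")
  v <- labels[is.finite(labels)]
  if (length(v) != length(labels) || any(v < 0) || any(v != floor(v)))
    stop("label image must contain non-negative integers (background = 0)")
  invisible(TRUE)
}

# Build CellGeometry records (plain lists) from a nuclei label image and a
# matching whole-cell label image (same label ids; cell sets are supersets
# of nucleus sets).
#' Build per-cell geometries from nuclei and whole-cell label images
#'
#' Each geometry is a list with fields `cell_id`, `nucleus_idx` and
#' `cell_idx` (linear pixel indices into the image matrix),
#' `nucleus_area_um2`, and `centroid_um` (`c(x, y)`, computed as the mean
#' of 0-based nucleus pixel centers scaled by the pixel size; x runs along
#' columns, y increases downward). The cytoplasm pixel set is
#' `cell_idx` minus `nucleus_idx` and may be empty.
#'
#' @param nuclei_labels Integer label matrix of nuclei (background 0).
#' @param cell_labels Integer label matrix of whole cells, same ids;
#'   defaults to the nuclei labels (no cytoplasm).
#' @param pixel_size_um Micrometres per pixel.
#' @return List of CellGeometry lists, ordered by ascending label id.
#' @export
cellGeometries <- function(nuclei_labels, cell_labels = nuclei_labels,
                           pixel_size_um) {
  .checkLabelImage(nuclei_labels)
  .checkLabelImage(cell_labels)
  if (!identical(dim(nuclei_labels), dim(cell_labels)))
    stop("nuclei and cell label images must have identical dimensions")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  if (length(ids) == 0) return(list())
  nr <- nrow(nuclei_labels)
  nidx <- split(which(nuclei_labels > 0),
                factor(nuclei_labels[nuclei_labels > 0], levels = ids))
  cidx <- split(which(cell_labels > 0),
                factor(cell_labels[cell_labels > 0], levels = ids))
  lapply(seq_along(ids), function(k) {
    ni <- nidx[[k]]
    ci <- sort(unique(c(cidx[[k]], ni)))   # nucleus pixels always included
    row <- ((ni - 1) %% nr) + 1
    col <- ((ni - 1) %/% nr) + 1
    list(cell_id = as.integer(ids[k]),
         nucleus_idx = ni,
         cell_idx = ci,
         nucleus_area_um2 = length(ni) * pixel_size_um^2,
         centroid_um = c(x = mean(col - 1) * pixel_size_um,
                         y = mean(row - 1) * pixel_size_um))
  })
}

#' Ingest an externally produced nuclei label image
#'
#' Wraps a label mask from an external segmenter (e.g. a StarDist export)
#' into per-cell geometries. Label ids are preserved; whole-cell pixel
#' sets initially equal the nucleus sets (apply [expandCells()] to grow
#' them).
#'
#' @param label_image Non-negative integer matrix, background 0.
#' @param pixel_size_um Micrometres per pixel.
#' @return List of CellGeometry lists (see [cellGeometries()]).
#' @export
ingestLabels <- function(label_image, pixel_size_um) {
  cellGeometries(label_image, label_image, pixel_size_um)
}

#' Built-in blob segmenter for synthetic nuclei
#'
#' A deterministic smoothed-threshold-watershed procedure intended for the
#' package's synthetic images: Gaussian smoothing of the nuclear channel,
#' Otsu (or fixed) thresholding, Euclidean distance transform, watershed
#' splitting of touching blobs, and removal of specks below a minimum
#' area.
#'
#' @param dapi 2D numeric matrix, nuclear-channel intensities.
#' @param pixel_size_um Micrometres per pixel.
#' @param sigma_um Smoothing sigma in micrometres (default 1).
#' @param threshold Intensity threshold on the smoothed image; `NULL`
#'   (default) uses Otsu's method.
#' @param min_area_um2 Minimum object area kept (default 2).
#' @return Integer label matrix with consecutive labels from 1.
#' @export
segmentNucleiBuiltin <- function(dapi, pixel_size_um, sigma_um = 1,
                                 threshold = NULL, min_area_um2 = 2) {
  stopIfNot2D(dapi, "dapi")
  sm <- gaussianSmooth(dapi, sigma_um / pixel_size_um)
  if (is.null(threshold)) {
    rng <- range(sm)
    if (diff(rng) <= 1e-8 * max(1, abs(rng[2])))   # flat image: no nuclei
      return(matrix(0L, nrow(dapi), ncol(dapi)))
    norm <- (sm - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  binary <- sm > threshold
  if (!any(binary)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  dm <- EBImage::distmap(binary * 1)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes * pixel_size_um^2 < min_area_um2)
  if (length(drop)) lab[lab %in% drop] <- 0
  # relabel consecutively, row-major discovery order
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Radially expand nuclei into non-overlapping whole-cell regions
#'
#' Grows each nucleus outward by at most `radius_um` (Euclidean metric
#' between pixel centers). Where expansions of neighboring nuclei meet,
#' pixels are partitioned by nearest-nucleus assignment; exact distance
#' ties go to the lower label id. Nucleus pixels always keep their own
#' label.
#'
#' @param nuclei_labels Integer label matrix (background 0).
#' @param radius_um Expansion radius in micrometres, `>= 0` (0 returns the
#'   input unchanged).
#' @param pixel_size_um Micrometres per pixel.
#' @return Integer whole-cell label matrix.
#' @export
expandCells <- function(nuclei_labels, radius_um, pixel_size_um) {
  .checkLabelImage(nuclei_labels)
  if (radius_um < 0) stop("radius_um must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  out <- nuclei_labels
  storage.mode(out) <- "integer"
  if (radius_um == 0) return(out)
  r_px <- radius_um / pixel_size_um
  r2 <- r_px^2
  nr <- nrow(nuclei_labels); nc <- ncol(nuclei_labels)
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  if (length(ids) == 0) return(out)
  # best squared distance to the owning nucleus per pixel; nucleus pixels
  # are locked with sentinel -1 so they are never reassigned
  best <- matrix(Inf, nr, nc)
  best[nuclei_labels > 0] <- -1
  owner <- out
  pad <- ceiling(r_px)
  for (id in ids) {
    pix <- which(nuclei_labels == id, arr.ind = TRUE)
    rr <- range(pix[, 1]); cr <- range(pix[, 2])
    rows <- max(1, rr[1] - pad):min(nr, rr[2] + pad)
    cols <- max(1, cr[1] - pad):min(nc, cr[2] + pad)
    box <- as.matrix(expand.grid(row = rows, col = cols))
    # exact integer squared distances between pixel centers
    d2 <- outer(box[, 1], pix[, 1], "-")^2 + outer(box[, 2], pix[, 2], "-")^2
    mind2 <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    ok <- mind2 <= r2
    bi <- box[ok, , drop = FALSE]
    md <- mind2[ok]
    cur <- best[bi]
    upd <- md < cur            # strict: ties keep the earlier (lower) id
    if (any(upd)) {
      best[bi[upd, , drop = FALSE]] <- md[upd]
      owner[bi[upd, , drop = FALSE]] <- id
    }
  }
  owner
}

#' Filter cells by nuclear area percentiles
#'
#' Discards cells whose nuclear area falls strictly below the `low_pct`
#' percentile or strictly above the `high_pct` percentile of the
#' per-image area distribution (percentiles by linear interpolation
#' between order statistics; cells exactly at a percentile are kept).
#' Such outliers typically represent debris, immune cells or fused nuclei.
#'
#' @param cells List of CellGeometry lists (see [cellGeometries()]).
#' @param low_pct,high_pct Percentile bounds in `[0, 100]`,
#'   `low_pct < high_pct`; defaults 5 and 99.
#' @return List with elements `kept` and `discarded` (both CellGeometry
#'   lists); together they partition the input.
#' @export
filterByArea <- function(cells, low_pct = 5, high_pct = 99) {
  if (length(cells) == 0) stop("no cells to filter")
  if (low_pct < 0 || high_pct > 100 || low_pct >= high_pct)
    stop("need 0 <= low_pct < high_pct <= 100")
  areas <- vapply(cells, function(g) g$nucleus_area_um2, numeric(1))
  lo <- linPercentile(areas, low_pct)
  hi <- linPercentile(areas, high_pct)
  keep <- !(areas < lo | areas > hi)
  list(kept = cells[keep], discarded = cells[!keep])
}

#' Read / write 16-bit label TIFFs
#'
#' @param labels Integer label matrix (values up to 65535).
#' @param path TIFF file path.
#' @return `writeLabelImage` returns `path` invisibly; `readLabelImage`
#'   returns an integer matrix.
#' @export
writeLabelImage <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeLabelImage
#' @export
readLabelImage <- function(path) {
  m <- tiff::readTIFF(path)
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}
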