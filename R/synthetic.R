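# Synthetic multiplexed tissue with full ground truth.
#
# Generates four-channel fields (DAPI nuclear stain, KER epithelial
# marker, FN stromal matrix, MARKER analysis marker) in which every
# quantity the pipeline later estimates is known exactly: nuclei label
# image, centroids, the stromal mask, each cell's signed distance to the
# stromal border, per-cell noiseless channel means, and binary
# cancer/marker classes. Per-cell intensities are drawn log-normally
# around their noiseless means, giving the right-skewed histograms
# characteristic of fluorescence data, and an affine batch shift emulates
# between-image staining variation.

#' Specification of a synthetic tissue image
#'
#' Collects and validates every generator parameter. All randomness in
#' [generateTissue()] flows from `seed`; identical specs give bit-identical
#' output.
#'
#' @param image_size_px Integer pair, image height (rows) and width (cols).
#' @param pixel_size_um Micrometres per pixel. The default of 1 um/px
#'   emulates a whole-slide field downsampled to desk scale: a 512 px
#'   field then spans 512 um, so stromal structures, the 50 um marker
#'   decay length and the [-100, 300) um profile range are all
#'   representable, and smoothing kernels stay small relative to tissue
#'   structure as they are on full-resolution slides. Set 0.3215 for
#'   native 20x scan resolution.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius_um Mean and SD of nucleus radius, micrometres.
#' @param stroma_fraction Target areal fraction of the stromal compartment,
#'   in (0, 1).
#' @param stroma_cell_density Relative cell density inside the stromal
#'   compartment (default 0.3): desmoplastic stroma is mostly acellular
#'   matrix, so far fewer cells sit inside it than outside, as seen in
#'   per-bin cell counts on real tissue.
#' @param stroma_mode `"blobs"` (thresholded smoothed noise, curvy
#'   contiguous regions) or `"half_plane"` (left vertical band; analytic
#'   distance ground truth).
#' @param marker_gradient List with `law` (`"exponential_decay"`,
#'   `"monotone_increase"` or `"flat"`), `amplitude`, `length_scale_um`,
#'   `baseline`: the distance law of the noiseless per-cell MARKER mean.
#' @param intensity_cv Log-normal shape (sdlog) of per-cell intensity
#'   draws around their noiseless means. The default (0.1) keeps per-cell
#'   draw noise small relative to the spatial gradient so that
#'   desk-scale fields (hundreds of cells, a handful per distance bin)
#'   retain the gradient structure that whole-slide images resolve
#'   through sheer cell numbers; raise it to stress-test classification
#'   under heavier biological variability.
#' @param batch_shift List with `scale` (multiplier, > 0) and `offset`
#'   applied to all generated intensities (staining batch effect).
#' @param noise_sd Additive Gaussian pixel noise SD, grey levels.
#' @param contamination Probability that a cell's cancer class violates the
#'   outside-stroma placement rule (exercises classifier errors).
#' @param marker_cut Raw-intensity cut defining ground-truth
#'   marker-positivity; `NULL` (default) uses the 90th percentile of the
#'   image's raw per-cell marker draws.
#' @param seed Integer seed.
#' @return A validated `TissueSpec` list (class `"TissueSpec"`).
#' @export
tissueSpec <- function(image_size_px = c(512, 512),
                       pixel_size_um = 1,
                       n_cells = 300,
                       nucleus_radius_um = c(mean = 3, sd = 0.4),
                       stroma_fraction = 0.3,
                       stroma_cell_density = 0.3,
                       stroma_mode = c("blobs", "half_plane"),
                       marker_gradient = list(law = "exponential_decay",
                                              amplitude = 100,
                                              length_scale_um = 50,
                                              baseline = 20),
                       intensity_cv = 0.1,
                       batch_shift = list(scale = 1, offset = 0),
                       noise_sd = 2,
                       contamination = 0.02,
                       marker_cut = NULL,
                       seed = 1) {
  stroma_mode <- match.arg(stroma_mode)
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 32),
            pixel_size_um > 0, n_cells >= 1,
            nucleus_radius_um[[1]] > 0, nucleus_radius_um[[2]] >= 0,
            stroma_fraction > 0, stroma_fraction < 1,
            stroma_cell_density > 0, stroma_cell_density <= 1,
            intensity_cv >= 0, batch_shift$scale > 0, noise_sd >= 0,
            contamination >= 0, contamination <= 1)
  law <- marker_gradient$law
  if (!law %in% c("exponential_decay", "monotone_increase", "flat"))
    stop("unknown marker_gradient law: ", law)
  if (law != "flat")
    stopifnot(marker_gradient$amplitude > 0,
              marker_gradient$length_scale_um > 0)
  stopifnot(marker_gradient$baseline >= 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 nucleus_radius_um = c(mean = nucleus_radius_um[[1]],
                                       sd = nucleus_radius_um[[2]]),
                 stroma_fraction = stroma_fraction,
                 stroma_cell_density = stroma_cell_density,
                 stroma_mode = stroma_mode,
                 marker_gradient = marker_gradient,
                 intensity_cv = intensity_cv, batch_shift = batch_shift,
                 noise_sd = noise_sd, contamination = contamination,
                 marker_cut = marker_cut, seed = as.integer(seed)),
            class = "TissueSpec")
}

# Noiseless marker mean as a function of signed distance (um). Inside the
# stroma (d < 0) the decay laws evaluate at d = 0.
.gradientMean <- function(gradient, d) {
  dp <- pmax(d, 0)
  switch(gradient$law,
    flat = rep(gradient$baseline, length(d)),
    exponential_decay = gradient$baseline +
      gradient$amplitude * exp(-dp / gradient$length_scale_um),
    monotone_increase = gradient$baseline +
      gradient$amplitude * (1 - exp(-dp / gradient$length_scale_um)))
}

# Stromal mask with areal fraction equal to the target (up to ties in the
# smoothed noise field, which is continuous). Blob mode thresholds a
# smooth low-frequency value-noise field (coarse uniform grid, bilinear
# upscale, light smoothing), giving one or a few contiguous curvy
# regions whose spatial scale is large relative to the stromal-model
# smoothing kernels, as in desmoplastic tissue.
.makeStromaMask <- function(nr, nc, fraction, mode) {
  if (mode == "half_plane") {
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    cols <= round(fraction * nc)
  } else {
    coarse <- matrix(runif(4 * 4), 4, 4)
    up <- EBImage::resize(EBImage::Image(coarse), w = nr, h = nc)
    sm <- gaussianSmooth(as.matrix(EBImage::imageData(up)),
                         min(nr, nc) / 16)
    m <- sm > stats::quantile(sm, 1 - fraction, names = FALSE)
    # drop sub-1% specks so the compartment stays a few large contiguous
    # regions, as in desmoplastic tissue
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(m * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= 0.01 * nr * nc)
    matrix(lab %in% keep, nr, nc)
  }
}

# Rejection-sample non-overlapping nucleus centers; candidates falling
# inside the stromal mask are additionally thinned to the relative
# stromal cell density. Errors when the requested density cannot be
# placed.
.placeNuclei <- function(n, radii_px, nr, nc, mask = NULL, density = 1,
                         max_attempts = 400L * n) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " non-overlapping nuclei in ", nr, "x", nc,
           " px after ", max_attempts, " attempts; lower n_cells or the ",
           "nucleus radius (density limit)")
    r <- radii_px[placed + 1L]
    cand <- c(runif(1, 1 + r, nr - r), runif(1, 1 + r, nc - r))
    if (!is.null(mask) && density < 1 &&
        mask[round(cand[1]), round(cand[2])] && runif(1) >= density)
      next
    if (placed > 0L) {
      prev <- centers[seq_len(placed), , drop = FALSE]
      d <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
      if (any(d <= r + radii_px[seq_len(placed)] + 1)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Paint value into a disk around (row, col) center; returns modified image.
.paintDisk <- function(img, row, col, radius_px, value, profile = c("flat", "gaussian")) {
  profile <- match.arg(profile)
  nr <- nrow(img); nc <- ncol(img)
  rows <- max(1, floor(row - radius_px)):min(nr, ceiling(row + radius_px))
  cols <- max(1, floor(col - radius_px)):min(nc, ceiling(col + radius_px))
  rg <- outer(rows - row, rep(1, length(cols)))
  cg <- outer(rep(1, length(rows)), cols - col)
  d2 <- rg^2 + cg^2
  inside <- d2 <= radius_px^2
  sub <- img[rows, cols, drop = FALSE]
  val <- if (profile == "flat") matrix(value, nrow(d2), ncol(d2))
         else value * exp(-d2 / (2 * (0.5 * radius_px)^2))
  sub[inside] <- pmax(sub[inside], val[inside])
  img[rows, cols] <- sub
  img
}

#' Generate a synthetic tissue image with ground truth
#'
#' See [tissueSpec()] for the generative model. Returns the four-channel
#' image stack and a ground-truth list carrying everything needed to
#' validate downstream stages.
#'
#' @param spec A `TissueSpec` from [tissueSpec()].
#' @return List with elements:
#'   \describe{
#'   \item{stack}{[ChannelStack-class] with channels `DAPI`, `KER`, `FN`,
#'     `MARKER` (batch-shifted, noisy grey levels).}
#'   \item{truth}{List: `nuclei_labels` (integer matrix, consecutive ids),
#'     `centroids_um` (n x 2, x/y), `stromal_mask` (logical matrix),
#'     `signed_distance_um` (per cell; negative inside the mask),
#'     `ker_positive`, `marker_positive` (logical), `marker_mean`
#'     (noiseless pre-shift MARKER mean per cell), `marker_raw` (per-cell
#'     pre-shift log-normal draw), `channel_means` (data.frame of
#'     noiseless pre-shift per-cell means), `marker_cut`, `radii_um`,
#'     `spec`.}
#'   }
#' @export
generateTissue <- function(spec) {
  stopifnot(inherits(spec, "TissueSpec"))
  withSeed(spec$seed, {
    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    ps <- spec$pixel_size_um
    n <- spec$n_cells

    mask <- .makeStromaMask(nr, nc, spec$stroma_fraction, spec$stroma_mode)

    radii_um <- pmax(rnorm(n, spec$nucleus_radius_um[["mean"]],
                           spec$nucleus_radius_um[["sd"]]),
                     spec$nucleus_radius_um[["mean"]] / 3)
    radii_px <- radii_um / ps
    centers <- .placeNuclei(n, radii_px, nr, nc, mask = mask,
                            density = spec$stroma_cell_density)

    # ground-truth signed distance from the true mask's border
    border <- .borderPixels(mask)
    cent_um <- pxToUm(centers[, 1], centers[, 2], ps)
    if (nrow(border) > 0) {
      bx <- (border[, "col"] - 1) * ps; by <- (border[, "row"] - 1) * ps
      mag <- vapply(seq_len(n), function(i)
        sqrt(min((cent_um[i, 1] - bx)^2 + (cent_um[i, 2] - by)^2)), numeric(1))
    } else mag <- rep(Inf, n)
    cpix <- cbind(round(centers[, 1]), round(centers[, 2]))
    inside <- mask[cpix]
    d_true <- mag * ifelse(inside, -1, 1)

    # classes: cancer (KER-high) cells exist only outside the stroma; a
    # small contamination fraction of the outside compartment is
    # non-cancer (KER-low), exercising classifier errors
    ker_pos <- !inside & runif(n) >= spec$contamination

    # noiseless per-cell channel means (pre batch shift)
    marker_mean <- .gradientMean(spec$marker_gradient, d_true)
    ker_mean <- ifelse(ker_pos, 150, 25)
    dapi_mean <- rep(180, n)

    sdlog <- spec$intensity_cv
    drawLN <- function(mu) {
      if (sdlog == 0) return(mu)
      rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }
    marker_raw <- drawLN(marker_mean)
    ker_raw <- drawLN(ker_mean)
    dapi_raw <- drawLN(dapi_mean)

    cut <- if (is.null(spec$marker_cut))
      stats::quantile(marker_raw, 0.9, names = FALSE) else spec$marker_cut
    marker_pos <- marker_raw > cut

    # paint channels
    labels <- matrix(0L, nr, nc)
    dapi <- matrix(0, nr, nc); ker <- matrix(0, nr, nc)
    marker <- matrix(0, nr, nc)
    cyto_px <- 5 / ps      # stains fill the cytoplasm out to ~5 um
    for (i in seq_len(n)) {
      rows <- max(1, floor(centers[i, 1] - radii_px[i])):
              min(nr, ceiling(centers[i, 1] + radii_px[i]))
      cols <- max(1, floor(centers[i, 2] - radii_px[i])):
              min(nc, ceiling(centers[i, 2] + radii_px[i]))
      d2 <- outer(rows - centers[i, 1], rep(1, length(cols)))^2 +
            outer(rep(1, length(rows)), cols - centers[i, 2])^2
      sub <- labels[rows, cols, drop = FALSE]
      sub[d2 <= radii_px[i]^2 & sub == 0L] <- i
      labels[rows, cols] <- sub
      dapi <- .paintDisk(dapi, centers[i, 1], centers[i, 2], radii_px[i],
                         dapi_raw[i], "gaussian")
      ker <- .paintDisk(ker, centers[i, 1], centers[i, 2],
                        radii_px[i] + cyto_px, ker_raw[i])
      marker <- .paintDisk(marker, centers[i, 1], centers[i, 2],
                           radii_px[i] + cyto_px, marker_raw[i])
    }
    fn <- gaussianSmooth(15 + 105 * mask, 2)

    shift <- function(img) spec$batch_shift$scale * img + spec$batch_shift$offset
    addNoise <- function(img) {
      if (spec$noise_sd == 0) return(img)
      pmax(img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0)
    }
    channels <- lapply(list(DAPI = dapi, KER = ker, FN = fn, MARKER = marker),
                       function(img) addNoise(shift(img)))

    list(stack = channelStack(channels, ps),
         truth = list(nuclei_labels = labels,
                      centroids_um = cent_um,
                      stromal_mask = mask,
                      signed_distance_um = d_true,
                      ker_positive = ker_pos,
                      marker_positive = marker_pos,
                      marker_mean = marker_mean,
                      marker_raw = marker_raw,
                      channel_means = data.frame(DAPI = dapi_mean,
                                                 KER = ker_mean,
                                                 MARKER = marker_mean),
                      marker_cut = cut,
                      radii_um = radii_um,
                      spec = spec))
  })
}

#' Write a synthetic tissue to disk
#'
#' Writes the channel stack as a multi-page 16-bit TIFF (one page per
#' channel), the nuclei label image as 16-bit TIFF, and a JSON
#' ground-truth sidecar (centroids, classes, distances, mask run-length
#' encoded, generator parameters).
#'
#' @param tissue Result of [generateTissue()].
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
writeTissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, "image.tif")
  lab_path <- file.path(dir, "nuclei_labels.tif")
  json_path <- file.path(dir, "ground_truth.json")
  writeChannelStack(tissue$stack, img_path)
  writeLabelImage(tissue$truth$nuclei_labels, lab_path)
  tr <- tissue$truth
  mask_rle <- rle(as.vector(tr$stromal_mask))
  obj <- list(
    pixel_size_um = pixelSize(tissue$stack),
    image_size_px = dim(tissue$stack),
    centroids_um = unname(apply(tr$centroids_um, 1, as.numeric, simplify = FALSE)),
    signed_distance_um = tr$signed_distance_um,
    ker_positive = tr$ker_positive,
    marker_positive = tr$marker_positive,
    marker_mean = tr$marker_mean,
    marker_raw = tr$marker_raw,
    marker_cut = tr$marker_cut,
    stromal_mask_rle = list(lengths = mask_rle$lengths,
                            values = mask_rle$values),
    spec = unclass(tr$spec))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(img_path, lab_path, json_path))
}
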