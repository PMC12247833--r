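# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package draw through this so that no
# function clobbers the global stream and identical seeds give identical
# results.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Percentile by linear interpolation between order statistics (the
# documented convention used for area filtering and display clipping).
linPercentile <- function(x, pct) {
  stats::quantile(x, probs = pct / 100, type = 7, names = FALSE)
}

# 0-based pixel-center coordinates (um) from 1-based matrix indices.
# x runs along columns, y along rows (y increases downward).
pxToUm <- function(row, col, pixel_size_um) {
  cbind(x = (col - 1) * pixel_size_um, y = (row - 1) * pixel_size_um)
}

# Containing pixel (1-based row/col) of a continuous um position; pixel
# (r, c) spans [c - 1.5, c - 0.5) * ps in x and likewise in y, i.e. pixel
# centers sit on the 0-based integer grid.
umToPx <- function(x_um, y_um, pixel_size_um, dims) {
  col <- pmin(pmax(floor(x_um / pixel_size_um + 0.5) + 1, 1), dims[2])
  row <- pmin(pmax(floor(y_um / pixel_size_um + 0.5) + 1, 1), dims[1])
  cbind(row = row, col = col)
}

# Gaussian smoothing in pixels; sigma 0 returns the input unchanged.
gaussianSmooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  out <- EBImage::gblur(img, sigma = sigma_px, boundary = "replicate")
  as.matrix(EBImage::imageData(out))
}

stopIfNot2D <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a 2D numeric matrix")
  invisible(TRUE)
}
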