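# Shared fixtures and independent oracles used across test files.

# Small, fast synthetic tissue for module tests.
smallTissue <- function(seed = 1, n_cells = 60, size = 192, ...) {
  generateTissue(tissueSpec(image_size_px = c(size, size), pixel_size_um = 1,
                            n_cells = n_cells, seed = seed, ...))
}

# Brute-force signed distance oracle: |d| = min distance from the point to
# any border pixel center; sign from mask membership of the containing
# pixel. Border rule: mask pixels with a non-mask 4-neighbor, image edge
# not counted as border.
oracleBorder <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    nb <- c(if (r > 1) mask[r - 1, c] else TRUE,
            if (r < nr) mask[r + 1, c] else TRUE,
            if (c > 1) mask[r, c - 1] else TRUE,
            if (c < nc) mask[r, c + 1] else TRUE)
    if (!all(nb)) out[r, c] <- TRUE
  }
  which(out, arr.ind = TRUE)
}

oracleSignedDistance <- function(mask, points_um, pixel_size_um) {
  border <- oracleBorder(mask)
  bx <- (border[, "col"] - 1) * pixel_size_um
  by <- (border[, "row"] - 1) * pixel_size_um
  vapply(seq_len(nrow(points_um)), function(i) {
    x <- points_um[i, 1]; y <- points_um[i, 2]
    mag <- sqrt(min((bx - x)^2 + (by - y)^2))
    col <- min(max(floor(x / pixel_size_um + 0.5) + 1, 1), ncol(mask))
    row <- min(max(floor(y / pixel_size_um + 0.5) + 1, 1), nrow(mask))
    if (mask[row, col]) -mag else mag
  }, numeric(1))
}

# Literal 2^n enumeration of the Wilcoxon signed-rank null for the
# two-sided exact p-value (zeros already dropped, average ranks).
oracleWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Sort-based percentile oracle (linear interpolation, type 7).
oraclePercentile <- function(x, pct) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * pct / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Random label image with k non-overlapping square nuclei.
randomNucleiLabels <- function(k, size = 48, half = 2, seed = 1) {
  set.seed(seed)
  lab <- matrix(0L, size, size)
  centers <- matrix(NA_real_, k, 2)
  placed <- 0L
  while (placed < k) {
    cand <- runif(2, half + 2, size - half - 1)
    if (placed > 0L &&
        min(pmax(abs(centers[seq_len(placed), 1] - cand[1]),
                 abs(centers[seq_len(placed), 2] - cand[2]))) < 2 * half + 2)
      next
    placed <- placed + 1L
    centers[placed, ] <- round(cand)
    lab[(centers[placed, 1] - half):(centers[placed, 1] + half),
        (centers[placed, 2] - half):(centers[placed, 2] + half)] <- placed
  }
  lab
}
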