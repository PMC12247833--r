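# Distance-binned marker intensity profiles.
#
# Cells are grouped into half-open signed-distance bins [k*w, (k+1)*w)
# aligned so that 0 um (the stromal border) is an edge; per bin the mean
# of a chosen intensity column is reported with a bootstrap standard
# error, and population differences carry error-propagated SEMs.

#' Assign cells to signed-distance bins
#'
#' Bin k covers `[k*w, (k+1)*w)` micrometres (half-open, 0 is always an
#' edge). Cells outside `range_um`, or with non-finite distance, receive
#' the sentinel `NA`.
#'
#' @param distances_um Numeric signed distances, micrometres.
#' @param bin_width_um Bin width, > 0 (default 10, about one cell
#'   diameter).
#' @param range_um Length-2 numeric, profile range (default
#'   `c(-100, 300)`); snapped outward to whole bins.
#' @return Integer vector of 1-based bin indices into the edge vector
#'   (`NA` = out of range), with the edges attached as
#'   `attr(, "edges")`.
#' @export
binCells <- function(distances_um, bin_width_um = 10,
                     range_um = c(-100, 300)) {
  if (bin_width_um <= 0) stop("bin_width_um must be positive")
  w <- bin_width_um
  edges <- seq(floor(range_um[1] / w) * w, ceiling(range_um[2] / w) * w,
               by = w)
  k <- floor(distances_um / w)                      # bin in units of w
  idx <- k - (edges[1] / w) + 1                     # 1-based into edges
  idx[!is.finite(distances_um) | idx < 1 | idx > length(edges) - 1] <- NA
  structure(as.integer(idx), edges = edges)
}

# Bootstrap SEM of the mean of v: SD of n_boot means of resamples with
# replacement. A single value gives 0 (all resamples identical).
.bootSEM <- function(v, n_boot) {
  n <- length(v)
  if (n == 0) return(NA_real_)
  if (n == 1) return(0)
  bm <- colMeans(matrix(sample(v, n * n_boot, replace = TRUE), n, n_boot))
  stats::sd(bm)
}

#' Distance-binned intensity profile of one cell population
#'
#' Bins the (optionally filtered) cells by signed distance and computes,
#' per bin, the cell count, the mean of `value_column`, the within-bin
#' sample standard deviation, and the bootstrap SEM of the bin mean
#' (`n_boot` resamples with replacement within the bin, seeded). Empty
#' bins get `NA` mean and SEM.
#'
#' @param table Cell table containing `distance_column` and
#'   `value_column`.
#' @param value_column Intensity column to profile.
#' @param subset Optional logical vector selecting the population (e.g.
#'   marker-positive cancer cells).
#' @param distance_column Signed-distance column name (default
#'   `"signed_distance_um"`).
#' @param bin_width_um,range_um Passed to [binCells()].
#' @param n_boot Bootstrap resamples per bin (default 500).
#' @param seed Seed for the bootstrap.
#' @param population_label Label stored on the profile.
#' @return A [BinProfile-class].
#' @export
distanceProfile <- function(table, value_column, subset = NULL,
                            distance_column = "signed_distance_um",
                            bin_width_um = 10, range_um = c(-100, 300),
                            n_boot = 500, seed = 1,
                            population_label = "") {
  for (col in c(distance_column, value_column))
    if (!col %in% names(table)) stop("column '", col, "' missing from table")
  if (!is.null(subset)) table <- table[which(subset), , drop = FALSE]
  d <- table[[distance_column]]
  v <- table[[value_column]]
  idx <- binCells(d, bin_width_um, range_um)
  edges <- attr(idx, "edges")
  k <- length(edges) - 1
  n <- integer(k); mu <- rep(NA_real_, k)
  sdv <- rep(NA_real_, k); sem <- rep(NA_real_, k)
  withSeed(seed, {
    for (b in seq_len(k)) {
      vb <- v[which(idx == b)]
      n[b] <- length(vb)
      if (n[b] > 0) {
        mu[b] <- mean(vb)
        sdv[b] <- if (n[b] > 1) stats::sd(vb) else NA_real_
        sem[b] <- .bootSEM(vb, n_boot)
      }
    }
  })
  binProfile(edges, n, mu, sdv, sem, population = population_label,
             column = value_column)
}

#' Bin-wise difference between two profiles with error propagation
#'
#' Per bin, the difference of means `a - b`; its standard error is
#' propagated from the within-bin standard deviations as
#' `sqrt(sd_a^2 / n_a + sd_b^2 / n_b)`. Bins empty (or with undefined SD)
#' in either input are `NA`.
#'
#' @param a,b [BinProfile-class] objects with identical bin edges.
#' @return A [BinProfile-class] of differences; the `sd` slot is `NA`
#'   (a difference of means has no single within-bin SD).
#' @export
profileDifference <- function(a, b) {
  stopifnot(is(a, "BinProfile"), is(b, "BinProfile"))
  if (!isTRUE(all.equal(a@binEdges, b@binEdges)))
    stop("profiles have different bin edges")
  k <- length(a@n)
  mu <- a@mean - b@mean
  sem <- sqrt(a@sd^2 / a@n + b@sd^2 / b@n)
  bad <- a@n == 0 | b@n == 0 | !is.finite(sem)
  mu[bad] <- NA_real_; sem[bad] <- NA_real_
  binProfile(a@binEdges, pmin(a@n, b@n), mu, sem = sem,
             population = paste0(a@population, " - ", b@population),
             column = a@column)
}

#' Plot a distance profile with error band and per-bin counts
#'
#' Line plot of the per-bin mean intensity against bin center with a
#' shaded +/- SEM band and a secondary axis showing the per-bin cell
#' count; the stromal border (0 um) is marked.
#'
#' @param profile A [BinProfile-class].
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data.frame of plotted values.
#' @export
plotProfile <- function(profile, main = profile@population, ...) {
  df <- as.data.frame(profile)
  mid <- (df$bin_left + df$bin_right) / 2
  ok <- !is.na(df$mean)
  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  graphics::plot(mid[ok], df$mean[ok], type = "n",
                 xlab = "signed distance to stromal border (um)",
                 ylab = profile@column, main = main, ...)
  band <- ok & !is.na(df$sem)
  graphics::polygon(c(mid[band], rev(mid[band])),
                    c(df$mean[band] + df$sem[band],
                      rev(df$mean[band] - df$sem[band])),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(mid[ok], df$mean[ok], type = "b", pch = 16)
  graphics::abline(v = 0, lty = 2)
  usr <- graphics::par("usr")
  scale <- (usr[4] - usr[3]) / max(1, max(df$n))
  graphics::lines(mid, usr[3] + df$n * scale * 0.25, col = "steelblue",
                  type = "s")
  graphics::axis(4, at = usr[3] + pretty(c(0, max(df$n))) * scale * 0.25,
                 labels = pretty(c(0, max(df$n))), col.axis = "steelblue")
  graphics::mtext("cells per bin", side = 4, line = 2.5, col = "steelblue")
  invisible(df)
}

#' Write a profile as CSV
#'
#' @param profile A [BinProfile-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, na = "")
  invisible(path)
}
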