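# Per-cell, per-compartment intensity statistics (the cell table).
#
# The cell table is a plain data.frame, one row per cell, with QuPath-
# compatible column names of the form "<Compartment>: <channel> <stat>"
# (e.g. "Nucleus: DAPI mean") so tables exported from QuPath can be used
# interchangeably. Raw grey levels throughout; no normalization.

.compartments <- c(Nucleus = "nucleus", Cytoplasm = "cytoplasm", Cell = "cell")
.stats <- c("mean", "median", "min", "max", "std")

.pixelStats <- function(v) {
  if (length(v) == 0)
    return(c(mean = NA_real_, median = NA_real_, min = NA_real_,
             max = NA_real_, std = NA_real_))
  m <- mean(v)
  c(mean = m, median = stats::median(v), min = min(v), max = max(v),
    std = sqrt(mean((v - m)^2)))   # population SD
}

#' Measure per-cell compartment intensity statistics
#'
#' For every cell and channel, computes mean, median, min, max and
#' (population) standard deviation over the nucleus, cytoplasm and
#' whole-cell pixel sets. Cytoplasm = cell pixels minus nucleus pixels;
#' when that set is empty its statistics are `NA`, never silently zero.
#' Values are raw grey levels over the exact pixel sets.
#'
#' @param stack A [ChannelStack-class].
#' @param geometries List of CellGeometry lists (see [cellGeometries()]).
#' @param image_id Image identifier stored in the `image_id` column.
#' @return A cell-table data.frame with columns `image_id`, `cell_id`,
#'   `centroid_x_um`, `centroid_y_um`, `nucleus_area_um2` and one
#'   `"<Compartment>: <channel> <stat>"` column per channel, compartment
#'   and statistic.
#' @export
measureCells <- function(stack, geometries, image_id = "image") {
  stopifnot(is(stack, "ChannelStack"))
  npx <- prod(dim(stack))
  nch <- channelNames(stack)
  n <- length(geometries)
  base <- data.frame(
    image_id = rep(image_id, n),
    cell_id = vapply(geometries, function(g) g$cell_id, integer(1)),
    centroid_x_um = vapply(geometries, function(g) g$centroid_um[["x"]], numeric(1)),
    centroid_y_um = vapply(geometries, function(g) g$centroid_um[["y"]], numeric(1)),
    nucleus_area_um2 = vapply(geometries, function(g) g$nucleus_area_um2, numeric(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (g in geometries) {
    if (length(g$nucleus_idx) == 0)
      stop("cell ", g$cell_id, " has an empty nucleus pixel set")
    if (any(g$cell_idx < 1 | g$cell_idx > npx))
      stop("cell ", g$cell_id, " has pixels outside the image")
  }
  cols <- list()
  for (ch in nch) {
    img <- getChannel(stack, ch)
    res <- vapply(geometries, function(g) {
      cyto <- setdiff(g$cell_idx, g$nucleus_idx)
      c(.pixelStats(img[g$nucleus_idx]),
        .pixelStats(img[cyto]),
        .pixelStats(img[g$cell_idx]))
    }, numeric(15))
    k <- 0
    for (comp in names(.compartments)) for (st in .stats) {
      k <- k + 1
      cols[[paste0(comp, ": ", ch, " ", st)]] <- res[k, ]
    }
  }
  cbind(base, as.data.frame(cols, check.names = FALSE, optional = TRUE))
}

#' Winsorize values at percentile bounds for display
#'
#' Clips a vector at its `low_pct` and `high_pct` percentiles (linear
#' interpolation). Intended only for histogram display to tame outliers;
#' never applied before classification or distribution fitting.
#'
#' @param values Non-empty numeric vector.
#' @param low_pct,high_pct Percentiles in `[0, 100]`; defaults 1 and 99.
#' @return Clipped numeric vector, same length.
#' @export
clipForDisplay <- function(values, low_pct = 1, high_pct = 99) {
  if (length(values) == 0) stop("values must be non-empty")
  lo <- linPercentile(values, low_pct)
  hi <- linPercentile(values, high_pct)
  pmin(pmax(values, lo), hi)
}

#' Write / read a cell table
#'
#' CSV (or tab-separated, by extension `.tsv`/`.txt`) serialization that
#' preserves the QuPath-style column names. The reader tolerates QuPath
#' measurement-table exports: tab- or comma-separated, with arbitrary
#' additional columns.
#'
#' @param table Cell-table data.frame.
#' @param path File path; `.tsv`/`.txt` write tab-separated.
#' @return `writeCellTable` returns `path` invisibly; `readCellTable`
#'   returns a data.frame with unmangled column names.
#' @export
writeCellTable <- function(table, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE, na = "",
                     quote = sep == ",")
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    quote = "\"", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, comment.char = "")
}
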