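# Sensitivity of spatial conclusions to stromal-model parameters.
#
# Robustness is characterized by re-deriving the stromal mask over a grid
# of (smoothing sigma, intensity threshold) values, recomputing signed
# distances and the Pearson correlation between marker intensity and
# distance separately for cells inside and outside the stroma, testing
# the inside/outside difference with an exact paired Wilcoxon signed-rank
# test, and bootstrapping correlation summaries across images.

#' Pearson correlation between intensity and distance
#'
#' Direct evaluation of the product-moment correlation
#' `sum((I - mean(I)) * (d - mean(d))) / sqrt(sum((I - mean(I))^2) *
#' sum((d - mean(d))^2))`.
#'
#' @param I Numeric vector of per-cell intensities.
#' @param d Numeric vector of per-cell signed distances, same length
#'   (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearsonR <- function(I, d) {
  if (length(I) != length(d)) stop("I and d must have equal length")
  if (length(I) < 3) stop("need at least 3 observations")
  ci <- I - mean(I); cd <- d - mean(d)
  den2 <- sum(ci^2) * sum(cd^2)
  if (den2 <= 0) stop("undefined correlation: zero variance in I or d")
  sum(ci * cd) / sqrt(den2)
}

# Exact null distribution of the positive-rank sum W, on doubled ranks so
# average (half-integer) ranks stay integral. Counts subsets of the rank
# multiset by the standard generating-function recursion, which equals
# full 2^n sign enumeration.
.wilcoxExactP <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)   # counts[s + 1] = #assignments with 2W = s
  counts[1] <- 1
  for (r in r2)
    counts[(r + 1):(total + 1)] <- counts[(r + 1):(total + 1)] +
                                   counts[1:(total + 1 - r)]
  w2 <- as.integer(round(2 * w))
  p_le <- sum(counts[seq_len(w2 + 1)]) / 2^length(r2)
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^length(r2)
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original rule); ties among
#' absolute differences receive average ranks. For `n <= 25` retained
#' pairs the two-sided p-value is exact over all `2^n` sign assignments;
#' above that a normal approximation with tie correction is used. With
#' all differences of the same sign the exact two-sided p is `2 / 2^n`.
#'
#' @param x,y Paired numeric vectors of equal length; at least 5 nonzero
#'   differences are required.
#' @return List with `statistic` (positive-rank sum W), `n` (retained
#'   pairs), `p.value`, and `exact` (logical).
#' @export
pairedWilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  if (length(d) == 0) stop("all differences are zero: test undefined")
  n <- length(d)
  if (n < 5) stop("need at least 5 nonzero differences, got ", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    p <- .wilcoxExactP(W, r)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- min(1, 2 * stats::pnorm(-abs(W - mu) / sqrt(sig2)))
    exact <- FALSE
  }
  list(statistic = W, n = n, p.value = p, exact = exact)
}

#' Sensitivity grid over stromal smoothing sigma and threshold
#'
#' For every `(sigma_um, threshold)` combination, rebuilds the stromal
#' model of each image, recomputes every cell's signed distance, splits
#' cells at the border (`d < 0` inside vs `d >= 0` outside), and computes
#' the Pearson correlation between `value_column` and distance on each
#' side. Grid points whose mask has no border are recorded as missing,
#' not fatal. Inside/outside correlations are compared with the paired
#' Wilcoxon test, and per-side means with standard errors are obtained by
#' bootstrapping over images (the resampling unit is the image).
#'
#' @param stacks Named list of [ChannelStack-class] objects (one per
#'   image), or a single stack.
#' @param tables Matching named list of cell tables (or one table) with
#'   centroid columns `centroid_x_um` / `centroid_y_um` and
#'   `value_column`.
#' @param sigmas_um Numeric vector of smoothing sigmas, micrometres.
#' @param thresholds Numeric vector of stromal intensity thresholds.
#' @param value_column Marker intensity column correlated with distance.
#' @param fn_channel Matrix channel name (default `"FN"`).
#' @param pairing Pairing unit for the Wilcoxon test:
#'   `"grid"` pairs every image-by-parameter combination, `"images"`
#'   pairs per-image medians across the grid.
#' @param n_boot Bootstrap iterations over images (default 500).
#' @param seed Seed for the bootstrap.
#' @param subset Optional named list of logical vectors (or one vector)
#'   restricting the cell population per image.
#' @return List of class `"SensitivityResult"`: `grid` (data.frame with
#'   sigma_um, threshold, image, r_inside, r_outside), `wilcoxon` (from
#'   [pairedWilcoxon()], or `NULL` if too few pairs), `bootstrap`
#'   (per-side mean and SE of r; SE `NULL` with a warning when fewer than
#'   3 images), `pairing`, `n_boot`.
#' @export
runSensitivityGrid <- function(stacks, tables, sigmas_um, thresholds,
                               value_column, fn_channel = "FN",
                               pairing = c("grid", "images"),
                               n_boot = 500, seed = 1, subset = NULL) {
  pairing <- match.arg(pairing)
  if (is(stacks, "ChannelStack")) stacks <- list(image = stacks)
  if (is.data.frame(tables)) tables <- setNames(list(tables), names(stacks)[1])
  if (!identical(sort(names(stacks)), sort(names(tables))))
    stop("stacks and tables must be named lists over the same images")
  if (length(sigmas_um) == 0 || length(thresholds) == 0)
    stop("sigma and threshold grids must be non-empty")
  if (!is.null(subset) && is.logical(subset))
    subset <- setNames(list(subset), names(stacks)[1])

  rows <- list()
  for (sg in sigmas_um) for (th in thresholds) for (id in names(stacks)) {
    tab <- tables[[id]]
    if (!is.null(subset)) tab <- tab[which(subset[[id]]), , drop = FALSE]
    model <- buildStromalModel(getChannel(stacks[[id]], fn_channel),
                               sigma_um = sg, threshold = th,
                               pixel_size_um = pixelSize(stacks[[id]]))
    if (nrow(stromalBorder(model)) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        sigma_um = sg, threshold = th, image = id,
        r_inside = NA_real_, r_outside = NA_real_)
      next
    }
    d <- signedDistance(model, tab[, c("centroid_x_um", "centroid_y_um")])
    I <- tab[[value_column]]
    rside <- function(side) {
      v <- I[side]; dd <- d[side]
      if (length(v) < 3) return(NA_real_)
      tryCatch(pearsonR(v, dd), error = function(e) NA_real_)
    }
    rows[[length(rows) + 1]] <- data.frame(
      sigma_um = sg, threshold = th, image = id,
      r_inside = rside(d < 0), r_outside = rside(d >= 0))
  }
  grid <- do.call(rbind, rows)

  pairs <- if (pairing == "grid") {
    stats::na.omit(grid[, c("r_inside", "r_outside")])
  } else {
    agg <- stats::aggregate(cbind(r_inside, r_outside) ~ image, grid,
                            stats::median, na.action = stats::na.omit)
    agg[, c("r_inside", "r_outside")]
  }
  wil <- tryCatch(pairedWilcoxon(pairs$r_inside, pairs$r_outside),
                  error = function(e) NULL)

  images <- names(stacks)
  meanSide <- function(g, side) mean(g[[side]], na.rm = TRUE)
  boot <- list(r_inside_mean = meanSide(grid, "r_inside"),
               r_outside_mean = meanSide(grid, "r_outside"),
               r_inside_se = NULL, r_outside_se = NULL)
  if (length(images) >= 3) {
    withSeed(seed, {
      bm <- vapply(seq_len(n_boot), function(b) {
        pick <- sample(images, length(images), replace = TRUE)
        g <- do.call(rbind, lapply(pick, function(id)
          grid[grid$image == id, , drop = FALSE]))
        c(meanSide(g, "r_inside"), meanSide(g, "r_outside"))
      }, numeric(2))
      boot$r_inside_se <- stats::sd(bm[1, ])
      boot$r_outside_se <- stats::sd(bm[2, ])
    })
  } else {
    warning("fewer than 3 images: bootstrap SE over images not reported")
  }
  structure(list(grid = grid, wilcoxon = wil, bootstrap = boot,
                 pairing = pairing, n_boot = n_boot),
            class = "SensitivityResult")
}

#' @export
print.SensitivityResult <- function(x, ...) {
  cat("SensitivityResult:", length(unique(x$grid$sigma_um)), "sigmas x",
      length(unique(x$grid$threshold)), "thresholds x",
      length(unique(x$grid$image)), "images\n")
  cat("  r_inside mean:", signif(x$bootstrap$r_inside_mean, 4),
      " r_outside mean:", signif(x$bootstrap$r_outside_mean, 4), "\n")
  if (!is.null(x$wilcoxon))
    cat("  paired Wilcoxon (", x$pairing, "): p = ",
        signif(x$wilcoxon$p.value, 4), "\n", sep = "")
  invisible(x)
}

#' Write sensitivity results (CSV grid + JSON summary)
#'
#' @param result A `"SensitivityResult"` from [runSensitivityGrid()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisible character vector of files written.
#' @export
writeSensitivityResult <- function(result, csv_path = NULL, json_path = NULL) {
  out <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(result$grid, csv_path, row.names = FALSE, na = "")
    out <- c(out, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      bootstrap = result$bootstrap,
      wilcoxon = result$wilcoxon,
      pairing = result$pairing, n_boot = result$n_boot),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
    out <- c(out, json_path)
  }
  invisible(out)
}
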