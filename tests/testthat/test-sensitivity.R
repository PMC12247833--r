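# Pearson correlation, exact Wilcoxon signed-rank, the parameter grid.

test_that("pearson r is exactly +/-1 on affine data", {
  x <- c(1.5, 2, 3.25, 7, 11, 13)
  expect_equal(pearsonR(x, x), 1, tolerance = 1e-12)
  expect_equal(pearsonR(x, -2 * x + 7), -1, tolerance = 1e-12)
})

test_that("pearson r equals the independent implementation on fixed vectors", {
  I <- c(3.2, 5.1, 0.4, 9.9, 2.2, 7.3, 6.6, 1.1, 8.8, 4.4)
  d <- c(12, 3, 45, 1, 30, 8, 5, 40, 2, 20)
  expect_equal(pearsonR(I, d), cor(I, d), tolerance = 1e-14)
})

test_that("degenerate correlations are rejected", {
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonR(1:2, 1:2), "at least 3")
  expect_error(pearsonR(1:4, 1:5), "equal length")
})

test_that("all-same-sign patterns give the exact two-sided 2/2^n", {
  r5 <- pairedWilcoxon(c(2, 3, 4, 5, 6), rep(0, 5))
  expect_equal(r5$p.value, 2 / 32)
  expect_true(r5$exact)
  r11 <- pairedWilcoxon(seq(2, 22, by = 2), rep(1, 11))
  expect_equal(r11$p.value, 2 / 2048)
})

test_that("exact p-values match literal 2^n enumeration for n <= 12", {
  set.seed(88)
  for (n in c(5, 6, 8, 10, 12)) {
    for (rep in 1:4) {
      d <- round(rnorm(n, 0.3, 1), 2)
      d[d == 0] <- 0.5
      got <- pairedWilcoxon(d, rep(0, n))
      expect_equal(got$p.value, oracleWilcoxonP(d), tolerance = 1e-12,
                   info = paste("n =", n))
    }
  }
})

test_that("exact p-values agree with wilcox.test when there are no ties", {
  set.seed(91)
  for (rep in 1:5) {
    x <- rnorm(15); y <- rnorm(15)
    if (anyDuplicated(abs(x - y))) next
    got <- pairedWilcoxon(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ties receive average ranks in the exact null", {
  d <- c(1, 1, 2, 2, 3, -1, -3)   # tied absolute differences
  got <- pairedWilcoxon(d + 5, rep(5, 7))
  expect_equal(got$p.value, oracleWilcoxonP(d), tolerance = 1e-12)
})

test_that("zero differences are dropped and degenerate input errors", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  expect_error(pairedWilcoxon(x, x), "zero")
  # zeros dropped: same p as without them
  a <- c(2, 3, 4, 5, 6); b <- rep(0, 5)
  with_zeros <- pairedWilcoxon(c(a, 9, 9), c(b, 9, 9))
  expect_equal(with_zeros$p.value, pairedWilcoxon(a, b)$p.value)
  expect_equal(with_zeros$n, 5)
  expect_error(pairedWilcoxon(c(1, 2, 3, 0), c(1, 2, 3, 1)), "at least 5")
})

test_that("large samples switch to the normal approximation smoothly", {
  set.seed(93)
  x <- rnorm(40, 0.5); y <- rnorm(40)
  got <- pairedWilcoxon(x, y)
  expect_false(got$exact)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("a decaying marker yields negative outside correlations across the grid", {
  tis <- generateTissue(tissueSpec(image_size_px = c(256, 256),
                                   pixel_size_um = 1, n_cells = 120,
                                   seed = 71))
  lab <- tis$truth$nuclei_labels
  g <- cellGeometries(lab, expandCells(lab, 5, 1), 1)
  tab <- measureCells(tis$stack, g, image_id = "img")
  fn <- getChannel(tis$stack, "FN")
  t0 <- quantile(as.vector(stromaSpatial:::gaussianSmooth(fn, 10)), 0.7,
                 names = FALSE)
  sens <- suppressWarnings(
    runSensitivityGrid(tis$stack, tab, c(5, 10, 15), t0 * c(0.8, 1, 1.2),
                       "Cell: MARKER max", seed = 4))
  expect_true(all(sens$grid$r_outside < 0))
  expect_true(all(sens$grid$r_inside >= -1 & sens$grid$r_inside <= 1))
})

test_that("a flat marker gives near-zero correlations on both sides", {
  # null case needs enough cells that sampling noise in r is << 0.1
  tis <- generateTissue(tissueSpec(
    image_size_px = c(800, 800), pixel_size_um = 1, n_cells = 2000,
    marker_gradient = list(law = "flat", amplitude = 1, length_scale_um = 1,
                           baseline = 60),
    seed = 73))
  lab <- tis$truth$nuclei_labels
  g <- cellGeometries(lab, expandCells(lab, 5, 1), 1)
  tab <- measureCells(tis$stack, g, image_id = "img")
  fn <- getChannel(tis$stack, "FN")
  t0 <- quantile(as.vector(stromaSpatial:::gaussianSmooth(fn, 10)), 0.7,
                 names = FALSE)
  sens <- suppressWarnings(
    runSensitivityGrid(tis$stack, tab, c(5, 10), t0 * c(0.9, 1.1),
                       "Cell: MARKER mean", seed = 4))
  expect_true(all(abs(sens$grid$r_outside) < 0.1, na.rm = TRUE))
  expect_true(all(abs(sens$grid$r_inside) < 0.1, na.rm = TRUE))
})

test_that("grid runs are deterministic given the seed", {
  tis <- smallTissue(seed = 79, n_cells = 40, size = 128)
  lab <- tis$truth$nuclei_labels
  g <- cellGeometries(lab, expandCells(lab, 5, 1), 1)
  tab <- measureCells(tis$stack, g, image_id = "img")
  run <- function() suppressWarnings(
    runSensitivityGrid(tis$stack, tab, c(5, 10), c(50, 60),
                       "Cell: MARKER max", seed = 2))
  expect_identical(run()$grid, run()$grid)
})

test_that("empty-border grid points are recorded as missing, not fatal", {
  tis <- smallTissue(seed = 83, n_cells = 30, size = 96)
  lab <- tis$truth$nuclei_labels
  g <- cellGeometries(lab, expandCells(lab, 5, 1), 1)
  tab <- measureCells(tis$stack, g, image_id = "img")
  sens <- suppressWarnings(
    runSensitivityGrid(tis$stack, tab, c(5), c(60, 1e6),
                       "Cell: MARKER max", seed = 2))
  hi <- sens$grid[sens$grid$threshold == 1e6, ]
  expect_true(all(is.na(hi$r_inside)) && all(is.na(hi$r_outside)))
  lo <- sens$grid[sens$grid$threshold == 60, ]
  expect_false(any(is.na(lo$r_outside)))
})

test_that("bootstrap summaries over >= 3 images are seeded and reported", {
  tabs <- list(); stacks <- list()
  for (i in 1:3) {
    tis <- smallTissue(seed = 100 + i, n_cells = 40, size = 128)
    lab <- tis$truth$nuclei_labels
    g <- cellGeometries(lab, expandCells(lab, 5, 1), 1)
    id <- paste0("img", i)
    tabs[[id]] <- measureCells(tis$stack, g, image_id = id)
    stacks[[id]] <- tis$stack
  }
  s1 <- runSensitivityGrid(stacks, tabs, c(8), c(60), "Cell: MARKER max",
                           n_boot = 100, seed = 6)
  s2 <- runSensitivityGrid(stacks, tabs, c(8), c(60), "Cell: MARKER max",
                           n_boot = 100, seed = 6)
  expect_false(is.null(s1$bootstrap$r_outside_se))
  expect_identical(s1$bootstrap, s2$bootstrap)
})
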