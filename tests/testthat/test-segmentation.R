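# Label ingestion, the built-in blob segmenter, expansion, area filter.

test_that("ingestLabels handles empty, unit and sparse-id label images", {
  expect_identical(ingestLabels(matrix(0L, 8, 8), 1), list())

  lab <- matrix(0L, 8, 8); lab[2:6, 3] <- 1L; lab[2:6, 4] <- 1L
  g <- ingestLabels(lab, 1)
  expect_length(g, 1)
  expect_equal(g[[1]]$nucleus_area_um2, 10)   # 10 px at 1 um/px
  expect_identical(g[[1]]$cell_idx, g[[1]]$nucleus_idx)

  lab2 <- matrix(0L, 10, 10)
  lab2[2, 2] <- 1L; lab2[5, 5] <- 3L; lab2[8, 8] <- 7L
  g2 <- ingestLabels(lab2, 2)
  expect_identical(vapply(g2, `[[`, integer(1), "cell_id"), c(1L, 3L, 7L))
  expect_equal(g2[[1]]$nucleus_area_um2, 4)   # 1 px at 2 um/px

  expect_error(ingestLabels(matrix(-1, 4, 4), 1), "non-negative")
  expect_error(ingestLabels(matrix(0.5, 4, 4), 1), "integer")
})

test_that("centroids are pixel-center means in um with x along columns", {
  lab <- matrix(0L, 6, 6)
  lab[3, 4:5] <- 1L    # row 3 (y = 2), cols 4 and 5 (x = 3 and 4)
  g <- ingestLabels(lab, 2)
  expect_equal(g[[1]]$centroid_um, c(x = 3.5 * 2, y = 2 * 2))
})

test_that("builtin segmenter recovers well-separated synthetic nuclei", {
  tis <- generateTissue(tissueSpec(image_size_px = c(224, 224),
                                   pixel_size_um = 1, n_cells = 50,
                                   seed = 31))
  lab <- segmentNucleiBuiltin(getChannel(tis$stack, "DAPI"), 1)
  expect_equal(max(lab), 50)
  expect_identical(segmentNucleiBuiltin(getChannel(tis$stack, "DAPI"), 1), lab)
})

test_that("builtin segmenter returns no labels on a blank image", {
  expect_equal(max(segmentNucleiBuiltin(matrix(0, 64, 64), 1)), 0)
  expect_equal(max(segmentNucleiBuiltin(matrix(5, 64, 64), 1)), 0)
})

test_that("watershed splits two disks one pixel apart", {
  img <- matrix(0, 48, 48)
  for (ctr in list(c(18, 24), c(31, 24))) {   # radius 6, edges 1 px apart
    d2 <- outer(seq_len(48) - ctr[1], rep(1, 48))^2 +
          outer(rep(1, 48), seq_len(48) - ctr[2])^2
    img[d2 <= 36] <- 100
  }
  lab <- segmentNucleiBuiltin(img, 1, sigma_um = 0.5)
  expect_equal(max(lab), 2)
})

test_that("expansion by zero radius is the identity", {
  lab <- randomNucleiLabels(5, seed = 3)
  expect_identical(expandCells(lab, 0, 1), lab)
  expect_error(expandCells(lab, -1, 1), ">= 0")
})

test_that("an isolated nucleus expands to the exact euclidean disk", {
  lab <- matrix(0L, 31, 31); lab[16, 16] <- 1L
  cells <- expandCells(lab, 5, 1)
  grid <- expand.grid(r = 1:31, c = 1:31)
  want <- (grid$r - 16)^2 + (grid$c - 16)^2 <= 25
  expect_identical(as.vector(cells == 1L), want)
  expect_equal(sum(cells == 1L), sum(want))   # brute-force disk pixel count
})

test_that("adjacent expansions partition space with ties to the lower id", {
  lab <- matrix(0L, 21, 21)
  lab[11, 9] <- 1L; lab[11, 13] <- 2L        # 4 px apart in x
  cells <- expandCells(lab, 5, 1)
  expect_equal(sum(cells == 1L & cells == 2L), 0)
  # the equidistant column (col 11) belongs to label 1 wherever labeled
  expect_true(all(cells[abs(seq_len(21) - 11) <= 4, 11] == 1L))
  expect_false(any(cells[, 11] == 2L))
  # brute-force nearest-nucleus assignment everywhere that is labeled
  for (r in 1:21) for (c in 1:21) {
    if (cells[r, c] == 0L) next
    d1 <- (r - 11)^2 + (c - 9)^2
    d2 <- (r - 11)^2 + (c - 13)^2
    expect_identical(cells[r, c], if (d1 <= d2) 1L else 2L)
  }
})

test_that("expansion is monotone in the radius", {
  lab <- randomNucleiLabels(6, size = 40, seed = 5)
  prev <- expandCells(lab, 1, 1)
  for (r in c(2, 4, 6)) {
    cur <- expandCells(lab, r, 1)
    grew <- prev > 0L
    expect_identical(cur[grew], prev[grew])
    prev <- cur
  }
})

test_that("expanded labels agree with brute-force nearest nuclei on random fixtures", {
  for (seed in 1:3) {
    lab <- randomNucleiLabels(4, size = 32, seed = seed)
    cells <- expandCells(lab, 4, 1)
    nuc <- which(lab > 0, arr.ind = TRUE)
    ids <- lab[nuc]
    for (r in 1:32) for (c in 1:32) {
      d2 <- (nuc[, 1] - r)^2 + (nuc[, 2] - c)^2
      best <- min(d2)
      want <- if (best <= 16) min(ids[d2 == best]) else 0L
      expect_identical(cells[r, c], as.integer(want))
    }
  }
})

test_that("area filter matches an independent percentile oracle", {
  set.seed(42)
  areas <- rlnorm(1000, 3, 0.4)
  lab_list <- lapply(seq_along(areas), function(i)
    list(cell_id = i, nucleus_idx = 1L, cell_idx = 1L,
         nucleus_area_um2 = areas[i], centroid_um = c(x = 0, y = 0)))
  flt <- filterByArea(lab_list)
  lo <- oraclePercentile(areas, 5); hi <- oraclePercentile(areas, 99)
  kept_areas <- vapply(flt$kept, `[[`, numeric(1), "nucleus_area_um2")
  expect_setequal(kept_areas, areas[!(areas < lo | areas > hi)])
  expect_length(flt$kept, 1000 - length(flt$discarded))
  expect_equal(length(flt$kept), sum(!(areas < lo | areas > hi)))
})

test_that("area filter keeps everything at 0/100 and under total ties", {
  g <- ingestLabels(randomNucleiLabels(5, seed = 9), 1)
  expect_length(filterByArea(g, 0, 100)$kept, 5)
  expect_length(filterByArea(g, 5, 99)$kept, 5)   # identical areas: all kept
  expect_error(filterByArea(list()), "no cells")
})

test_that("area filter is idempotent on its own kept set", {
  set.seed(7)
  areas <- rlnorm(300, 3, 0.5)
  cells <- lapply(seq_along(areas), function(i)
    list(cell_id = i, nucleus_idx = 1L, cell_idx = 1L,
         nucleus_area_um2 = areas[i], centroid_um = c(x = 0, y = 0)))
  kept <- filterByArea(cells)$kept
  again <- filterByArea(kept, 0, 100)$kept
  expect_identical(length(again), length(kept))
})
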