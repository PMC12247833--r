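# Synthetic tissue generator: determinism, ground-truth laws, invariants.

test_that("generation is a pure function of the spec and seed", {
  a <- smallTissue(seed = 5)
  b <- smallTissue(seed = 5)
  expect_identical(a$stack@channels, b$stack@channels)
  expect_identical(a$truth$signed_distance_um, b$truth$signed_distance_um)
  c <- smallTissue(seed = 6)
  expect_false(identical(a$truth$centroids_um, c$truth$centroids_um))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(smallTissue(seed = 3))
  expect_identical(before, .Random.seed)
})

test_that("stromal mask areal fraction matches the target", {
  for (frac in c(0.2, 0.3, 0.5)) {
    tis <- generateTissue(tissueSpec(image_size_px = c(256, 256),
                                     pixel_size_um = 1, n_cells = 20,
                                     stroma_fraction = frac, seed = 4))
    expect_lt(abs(mean(tis$truth$stromal_mask) - frac), 0.05)
  }
})

test_that("nuclei labels are consecutive, disjoint disks matching centroids", {
  tis <- smallTissue(seed = 2)
  lab <- tis$truth$nuclei_labels
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(ids, seq_len(tis$truth$spec$n_cells))
  # no nucleus pixel is shared and every cell has pixels
  expect_true(all(tabulate(lab[lab > 0]) > 0))
})

test_that("flat gradient makes every noiseless marker mean the baseline", {
  tis <- generateTissue(tissueSpec(
    image_size_px = c(160, 160), pixel_size_um = 1, n_cells = 30,
    marker_gradient = list(law = "flat", amplitude = 1,
                           length_scale_um = 1, baseline = 37),
    noise_sd = 0, seed = 3))
  expect_true(all(tis$truth$marker_mean == 37))
})

test_that("exponential-decay law holds cell by cell against ground truth", {
  tis <- smallTissue(seed = 8)
  g <- tis$truth$spec$marker_gradient
  d <- tis$truth$signed_distance_um
  expected <- g$baseline + g$amplitude * exp(-pmax(d, 0) / g$length_scale_um)
  expect_equal(tis$truth$marker_mean, expected, tolerance = 1e-12)
})

test_that("monotone-increase law rises with distance outside the stroma", {
  tis <- generateTissue(tissueSpec(
    image_size_px = c(192, 192), pixel_size_um = 1, n_cells = 50,
    marker_gradient = list(law = "monotone_increase", amplitude = 80,
                           length_scale_um = 50, baseline = 10), seed = 9))
  d <- tis$truth$signed_distance_um
  m <- tis$truth$marker_mean
  ord <- order(d)
  expect_true(all(diff(m[ord][d[ord] >= 0]) >= -1e-12))
  expect_true(all(m[d <= 0] == 10))
})

test_that("true signed distance is negative exactly inside the mask", {
  tis <- smallTissue(seed = 12)
  mask <- tis$truth$stromal_mask
  cent <- tis$truth$centroids_um
  px <- cbind(floor(cent[, 2] + 0.5) + 1, floor(cent[, 1] + 0.5) + 1)
  expect_identical(tis$truth$signed_distance_um < 0, unname(mask[px]))
})

test_that("batch shift preserves the rank order of per-cell intensities", {
  base <- generateTissue(tissueSpec(image_size_px = c(160, 160),
                                    pixel_size_um = 1, n_cells = 40,
                                    seed = 21))
  shifted <- generateTissue(tissueSpec(image_size_px = c(160, 160),
                                       pixel_size_um = 1, n_cells = 40,
                                       batch_shift = list(scale = 2.2,
                                                          offset = 10),
                                       seed = 21))
  expect_identical(order(base$truth$marker_raw),
                   order(shifted$truth$marker_raw))
  # raw (pre-shift) draws are identical; the observed image is shifted
  expect_equal(base$truth$marker_raw, shifted$truth$marker_raw)
  expect_gt(mean(getChannel(shifted$stack, "MARKER")),
            mean(getChannel(base$stack, "MARKER")))
})

test_that("impossible densities raise an error naming the limit", {
  expect_error(
    generateTissue(tissueSpec(image_size_px = c(64, 64), pixel_size_um = 1,
                              n_cells = 200, seed = 1)),
    "density limit")
})

test_that("tissue round-trips through the TIFF + JSON sidecar writer", {
  tis <- smallTissue(seed = 14, n_cells = 20, size = 96)
  dir <- withr::local_tempdir()
  files <- writeTissue(tis, dir)
  expect_true(all(file.exists(files)))
  back <- readChannelStack(file.path(dir, "image.tif"))
  expect_identical(channelNames(back), channelNames(tis$stack))
  expect_equal(pixelSize(back), 1)
  # 16-bit storage quantizes to ~1 grey level
  expect_lt(max(abs(getChannel(back, "MARKER") -
                    getChannel(tis$stack, "MARKER"))), 1)
  lab <- readLabelImage(file.path(dir, "nuclei_labels.tif"))
  expect_identical(lab, tis$truth$nuclei_labels)
})
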