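# Distribution fitting, percentile mapping, threshold propagation.

test_that("log-normal and gamma samples are identified with parameter recovery", {
  x <- withr::with_seed(101, rlnorm(20000, meanlog = 3, sdlog = 0.5))
  fit <- fitBestDistribution(x)
  expect_identical(fit@family, "lnorm")
  expect_lt(abs(fit@estimate[["meanlog"]] - 3) / 3, 0.05)
  expect_lt(abs(fit@estimate[["sdlog"]] - 0.5) / 0.5, 0.05)

  g <- withr::with_seed(102, rgamma(20000, shape = 2, scale = 50))
  fitg <- fitBestDistribution(g)
  expect_identical(fitg@family, "gamma")
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fitBestDistribution(rep(10, 50)), "degenerate")
  expect_error(fitBestDistribution(rlnorm(30)), "at least 50")
})

test_that("non-positive values are excluded with a message but counted", {
  x <- withr::with_seed(7, rlnorm(500, 3, 0.5))
  expect_message(fit <- fitBestDistribution(c(x, 0, -5, -1)), "3 non-positive")
  expect_identical(fit@nExcluded, 3L)
  expect_identical(fit@nSamples, 500L)
})

test_that("percentile mapping has the log-normal closed forms", {
  fit <- new("FittedDistribution", family = "lnorm",
             estimate = c(meanlog = 2, sdlog = 0.7), sse = 0,
             histBinWidth = 1, nSamples = 100L, nExcluded = 0L)
  expect_equal(thresholdToPercentile(fit, exp(2)), 0.5)
  expect_equal(percentileToThreshold(fit, 0.5), exp(2))
  # CDF limit towards 1 for large thresholds
  expect_gt(thresholdToPercentile(fit, exp(2 + 10 * 0.7)), 1 - 1e-9)
  expect_error(thresholdToPercentile(fit, -1), "positive")
  expect_error(percentileToThreshold(fit, 1), "inside")
  expect_error(percentileToThreshold(fit, 0), "inside")
})

test_that("quantiles agree with an independent bisection inversion of the CDF", {
  fit <- new("FittedDistribution", family = "lnorm",
             estimate = c(meanlog = 0, sdlog = 1), sse = 0,
             histBinWidth = 1, nSamples = 100L, nExcluded = 0L)
  for (p in c(0.1, 0.5, 0.9)) {
    lo <- 1e-9; hi <- 1e9
    for (i in 1:200) {
      mid <- sqrt(lo * hi)   # geometric bisection on positive support
      if (plnorm(mid) < p) lo <- mid else hi <- mid
    }
    expect_equal(percentileToThreshold(fit, p), sqrt(lo * hi),
                 tolerance = 1e-6)
  }
  expect_lt(percentileToThreshold(fit, 0.1), percentileToThreshold(fit, 0.9))
})

test_that("threshold/percentile round-trips are tight", {
  x <- withr::with_seed(11, rlnorm(5000, 3, 0.4))
  fit <- fitBestDistribution(x)
  for (thr in c(10, 20, 40)) {
    p <- thresholdToPercentile(fit, thr)
    expect_equal(percentileToThreshold(fit, p), thr, tolerance = 1e-6)
  }
})

test_that("self-propagation returns the reference threshold", {
  x <- withr::with_seed(12, rlnorm(5000, 3, 0.4))
  tab <- data.frame(v = x); names(tab) <- "Cell: M max"
  map <- propagateThresholds(list(ref = tab), "Cell: M max", "ref", 30)
  expect_equal(unname(map@thresholds[["ref"]]), 30, tolerance = 1e-6)
  expect_equal(map@percentile,
               thresholdToPercentile(map@fits$ref, 30))
})

test_that("a pure batch scale translates the threshold by the same factor", {
  x <- withr::with_seed(13, rlnorm(20000, 3, 0.5))
  mk <- function(v) { tab <- data.frame(v = v); names(tab) <- "Cell: M max"; tab }
  thr <- quantile(x, 0.9, names = FALSE)
  for (cc in c(1.6, 2.0)) {
    map <- propagateThresholds(list(ref = mk(x), tgt = mk(cc * x)),
                               "Cell: M max", "ref", thr)
    expect_lt(abs(map@thresholds[["tgt"]] - cc * map@thresholds[["ref"]]) /
              (cc * map@thresholds[["ref"]]), 0.02)
    # positive fractions match across the pair
    f_ref <- mean(x > map@thresholds[["ref"]])
    f_tgt <- mean(cc * x > map@thresholds[["tgt"]])
    expect_lt(abs(f_ref - f_tgt), 0.005)
  }
})

test_that("percentile preservation holds under the fitted CDFs", {
  x <- withr::with_seed(14, rlnorm(8000, 3, 0.5))
  y <- withr::with_seed(15, rlnorm(8000, 3.7, 0.6))
  mk <- function(v) { tab <- data.frame(v = v); names(tab) <- "Cell: M max"; tab }
  map <- propagateThresholds(list(a = mk(x), b = mk(y)), "Cell: M max", "a",
                             quantile(x, 0.85, names = FALSE))
  for (id in c("a", "b"))
    expect_equal(thresholdToPercentile(map@fits[[id]], map@thresholds[[id]]),
                 map@percentile, tolerance = 1e-9)
})

test_that("affine monotone transforms are tracked equivariantly", {
  # target = g(reference) with g(x) = 2x (affine, order preserving);
  # log-normal closure means the translated threshold is g(reference one)
  x <- withr::with_seed(16, rlnorm(20000, 2.5, 0.45))
  mk <- function(v) { tab <- data.frame(v = v); names(tab) <- "Cell: M max"; tab }
  thr <- quantile(x, 0.8, names = FALSE)
  map <- propagateThresholds(list(r = mk(x), t = mk(2 * x)),
                             "Cell: M max", "r", thr)
  expect_equal(unname(map@thresholds[["t"]]),
               2 * unname(map@thresholds[["r"]]), tolerance = 0.02)
})

test_that("fit failure on one image names the image", {
  good <- data.frame(v = withr::with_seed(17, rlnorm(500, 3, 0.4)))
  names(good) <- "Cell: M max"
  bad <- data.frame(v = rep(5, 60)); names(bad) <- "Cell: M max"
  expect_error(
    propagateThresholds(list(ok = good, broken = bad), "Cell: M max", "ok", 20),
    "broken")
})

test_that("threshold maps survive JSON round-trips", {
  x <- withr::with_seed(18, rlnorm(2000, 3, 0.5))
  mk <- function(v) { tab <- data.frame(v = v); names(tab) <- "Cell: M max"; tab }
  map <- propagateThresholds(list(a = mk(x), b = mk(1.5 * x)),
                             "Cell: M max", "a", 25)
  p <- withr::local_tempfile(fileext = ".json")
  writeThresholdMap(map, p)
  back <- readThresholdMap(p)
  expect_equal(back@thresholds, map@thresholds)
  expect_equal(back@percentile, map@percentile)
  expect_identical(back@fits$b@family, map@fits$b@family)
  expect_equal(back@fits$b@estimate, map@fits$b@estimate)
})
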