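linearCal <- function() {
  w <- c(20000, 10000, 5000, 2000, 1000, 500)
  fit <- fitLadder(ladderBands(100 * (5 - log10(w)), w), "linear")
  ladderCalibration(fit)
}

test_that("profile extraction reproduces per-row lane means mapped to weight", {
  cal <- linearCal()
  m <- matrix(0, 300, 20)
  vals <- 100 + 50 * sin(seq_len(300) / 15)
  m[, 6:15] <- vals
  img <- new("GelImage", raw = m, bitDepth = 16L)
  p <- extractIntensityProfile(img, 5, 15, cal)
  o <- order(p@row)
  expect_equal(p@intensity[o], vals[p@row[o]])
  expect_true(all(diff(p@mw) > 0))
  expect_equal(p@mw, suppressWarnings(pixelToMw(cal, p@row)), tolerance = 1e-9)

  # constant lane stays constant; one-column lane equals that column
  m2 <- m; m2[, 6:15] <- 7
  p2 <- extractIntensityProfile(new("GelImage", raw = m2, bitDepth = 16L), 5, 15, cal)
  expect_true(all(p2@intensity == 7))
  p3 <- extractIntensityProfile(img, 5, 6, cal)
  expect_equal(sort(p3@intensity), sort(m[p3@row, 6]))
})

test_that("background options implement the minimum-window trendline and baseline rules", {
  cal <- linearCal()
  n <- 40
  rows <- 101:140
  mk <- function(I) new("IntensityProfile",
                        mw = rev(pixelToMw(cal, rows)), intensity = rev(I),
                        row = rev(rows))
  # constant 7, baseline: all zero
  expect_true(all(subtractBackground(mk(rep(7, n)), "baseline")@intensity == 0))

  # first-window min 5, last-window min 9: trendline subtracts 7 at the midpoint
  I <- c(5 + (0:9) / 10, rep(20, n - 20), 9 + (9:0) / 10)
  tr <- subtractBackground(mk(I), "trendline")
  o <- order(tr@row)
  mid <- tr@intensity[o][(n / 2)]
  line <- 5 + (9 - 5) * ((n / 2) - 1) / (n - 1)
  expect_equal(mid, 20 - line, tolerance = 1e-9)
  bl <- subtractBackground(mk(I), "baseline")
  expect_equal(bl@intensity[o][n / 2], 20 - 7, tolerance = 1e-9)

  # manual with region mean 0 is the identity; missing mean is an error
  expect_equal(subtractBackground(mk(I), "manual", manualRegionMean = 0)@intensity,
               mk(I)@intensity)
  expect_error(subtractBackground(mk(I), "manual"), "manualRegionMean")

  # negative clipping policy
  clip <- subtractBackground(mk(I), "manual", manualRegionMean = 8)
  expect_true(all(clip@intensity >= 0))
  neg <- subtractBackground(mk(I), "manual", manualRegionMean = 8,
                            allowNegative = TRUE)
  expect_true(any(neg@intensity < 0))

  rowsShort <- 101:115
  short <- new("IntensityProfile",
               mw = rev(pixelToMw(cal, rowsShort)),
               intensity = rep(7, 15), row = rev(rowsShort))
  expect_error(subtractBackground(short, "trendline"), "20 points")
})

test_that("the Gaussian fit recovers exact parameters from noiseless profiles", {
  p <- gaussProfile(a = 2, mu = 5000, sigma = 800)
  f <- fitGaussian(p)
  expect_equal(f@a, 2, tolerance = 1e-6)
  expect_equal(f@mu, 5000, tolerance = 1e-6)
  expect_equal(f@sigma, 800, tolerance = 1e-6)
  expect_equal(f@q, 1, tolerance = 1e-9)
  expect_true(f@converged)
  expect_lte(f@iterations, 50L)

  # exact recovery also after removing a constant baseline exactly
  p2 <- p
  p2@intensity <- p@intensity + 0.5
  p2 <- subtractBackground(p2, "baseline")
  f2 <- fitGaussian(p2)
  expect_equal(f2@mu, 5000, tolerance = 1e-4)
})

test_that("fit quality is invariant to positive intensity scaling", {
  p <- gaussProfile(a = 1, mu = 4000, sigma = 600)
  set.seed(5)
  p@intensity <- p@intensity + rnorm(length(p@mw), sd = 0.05)
  p@intensity <- pmax(p@intensity, 0)
  f1 <- fitGaussian(p)
  pk <- p
  pk@intensity <- 37.5 * p@intensity
  fk <- fitGaussian(pk)
  expect_equal(fk@q, f1@q, tolerance = 1e-8)
  expect_equal(fk@mu, f1@mu, tolerance = 1e-6)
  expect_equal(fk@sigma, f1@sigma, tolerance = 1e-6)
  expect_equal(fk@a, 37.5 * f1@a, tolerance = 1e-6)
})

test_that("the fit is deterministic: identical input gives identical output", {
  p <- gaussProfile()
  set.seed(8)
  p@intensity <- p@intensity + abs(rnorm(length(p@mw), sd = 0.1))
  f1 <- fitGaussian(p)
  f2 <- fitGaussian(p)
  expect_identical(f1@mu, f2@mu)
  expect_identical(f1@sigma, f2@sigma)
  expect_identical(f1@q, f2@q)
  expect_identical(f1@iterations, f2@iterations)
})

test_that("a well-separated two-peak profile is flagged by low fit quality", {
  x <- seq(1000, 15000, length.out = 300)
  I <- exp(-(x - 4000)^2 / (2 * 600^2)) + exp(-(x - 11000)^2 / (2 * 600^2))
  p <- new("IntensityProfile", mw = x, intensity = I, row = rev(seq_along(x)))
  f <- fitGaussian(p)
  expect_lt(f@q, 0.95)

  # independent oracle: best single-Gaussian q over a dense parameter scan
  best <- -Inf
  tss <- sum((I - mean(I))^2)
  for (mu in seq(2000, 13000, by = 250)) {
    for (sg in seq(300, 6000, by = 150)) {
      g <- exp(-(x - mu)^2 / (2 * sg^2))
      a <- sum(g * I) / sum(g * g)
      q <- 1 - sum((I - a * g)^2) / tss
      if (q > best) best <- q
    }
  }
  expect_lt(best, 0.95)
})

test_that("degenerate profiles are rejected", {
  x <- seq(1000, 2000, length.out = 30)
  zero <- new("IntensityProfile", mw = x, intensity = rep(0, 30),
              row = rev(seq_along(x)))
  expect_error(fitGaussian(zero), "degenerate")
  short <- gaussProfile(n = 5)
  expect_error(fitGaussian(short), "10 points")
})
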