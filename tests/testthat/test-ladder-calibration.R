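test_that("goodness of fit reproduces hand-computed R2 and adjusted R2", {
  g <- goodnessOfFit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), d = 1)
  expect_equal(g$rss, 0.10, tolerance = 1e-12)
  expect_equal(g$tss, 5.0, tolerance = 1e-12)
  expect_equal(g$r2, 0.98, tolerance = 1e-12)
  expect_equal(g$r2adj, 0.97, tolerance = 1e-12)

  perfect <- goodnessOfFit(1:4, 1:4, d = 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2adj, 1)

  # modeled = mean(observed) at d = 0 gives r2 = 0 by definition
  atMean <- goodnessOfFit(c(1, 2, 3, 4), rep(2.5, 4), d = 0)
  expect_equal(atMean$r2, 0)

  expect_error(goodnessOfFit(rep(2, 5), rep(2, 5), d = 1), "degenerate")
})

test_that("adjusted R2 never exceeds R2, with equality only at r2 = 1 or d = 0", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    d <- sample(0:3, 1)
    obs <- rnorm(n)
    mod <- obs + rnorm(n, sd = 0.3)
    g <- goodnessOfFit(obs, mod, d)
    expect_lte(g$r2adj, g$r2 + 1e-12)
    if (d > 0 && g$r2 < 1) expect_lt(g$r2adj, g$r2)
  }
  g0 <- goodnessOfFit(c(1, 2, 4), c(1.2, 2.2, 3.5), d = 0)
  expect_equal(g0$r2adj, g0$r2)
})

test_that("the cubic model recovers cubic migration exactly; nested models rank by adjusted R2", {
  lw <- log10(c(20000, 10000, 6000, 4000, 2500, 1500, 1000, 750, 500))
  rows <- 400 - 20 * lw - 8 * lw^2 - 1.5 * lw^3
  bands <- ladderBands(sort(rows), sort(10^lw, decreasing = TRUE))

  cubic <- fitLadder(bands, "poly3")
  expect_gte(cubic@r2, 1 - 1e-9)
  expect_identical(cubic@model, "poly3")
  expect_identical(fitLadder(bands, "auto")@model, "poly3")

  lin <- fitLadder(bands, "linear")
  expect_lt(lin@r2, 1)
  expect_lt(lin@r2adj, cubic@r2adj)

  expect_error(fitLadder(ladderBands(rows[1:4], 10^lw[1:4]), "poly3"),
               "at least 5")
})

test_that("reciprocal and spline calibration models fit monotone ladders", {
  lw <- log10(c(20000, 10000, 6000, 4000, 2500, 1500, 1000, 750, 500))
  rows <- sort(500 - 100 * lw)
  bands <- ladderBands(rows, 10^sort(lw, decreasing = TRUE))
  for (model in c("reciprocal", "spline")) {
    fit <- expect_silent(fitLadder(bands, model))
    expect_gte(fit@r2, 0.99)
    grid <- seq(fit@lwRange[1], fit@lwRange[2], length.out = 100)
    expect_true(all(diff(fit@predictRow(grid)) < 0))
  }
})

test_that("ladder bands are detected within a pixel of their true rows", {
  gel <- noiselessGel(seed = 2)
  truth <- gel$truth
  lane <- truth$lanes[1, ]
  bands <- detectLadderBands(gel$image, lane$colStart, lane$colEnd)
  got <- assignLadderWeights(bands, truth$ladderWeights)
  expect_equal(length(got@rows), length(truth$ladderRows))
  expect_true(all(abs(got@rows - truth$ladderRows) <= 1))
})

test_that("flat ladder lanes and blur-merged bands behave as documented", {
  flat <- new("GelImage", raw = matrix(50, 120, 30), bitDepth = 8L)
  expect_error(detectLadderBands(flat, 5, 25), "flat|insufficient")

  # bands at rows 40/60/80 plus a close pair at 100 and 104 that the
  # smoothing merges into a single maximum between them
  rows <- 1:150
  prof <- 200 * (dnorm(rows, 40, 1.5) + dnorm(rows, 60, 1.5) +
                 dnorm(rows, 80, 1.5) + dnorm(rows, 100, 1.5) +
                 dnorm(rows, 104, 1.5))
  img <- new("GelImage", raw = matrix(rep(prof, 10), ncol = 10), bitDepth = 8L)
  got <- detectLadderBands(img, 0, 10)
  inPair <- got$row[got$row > 95 & got$row < 109]
  expect_equal(length(inPair), 1)
  expect_true(inPair > 100 && inPair < 104)
})

test_that("pixel-to-weight inversion matches the closed-form migration inverse", {
  # migration row = 100 (5 - log10 w): bands at 10000/3000/1000 nt
  w <- c(10000, 3000, 1000)
  rows <- 100 * (5 - log10(w))
  fit <- fitLadder(ladderBands(rows, w), "linear")
  cal <- ladderCalibration(fit)
  expect_equal(pixelToMw(cal, 150), 10^3.5, tolerance = 0.01)
  expect_equal(pixelToMw(cal, rows[2]), 3000, tolerance = 1e-6)
})

test_that("dual-ladder interpolation is exact at the flanks and inert when identical", {
  gel <- noiselessGel(seed = 3)
  bands <- ladderBands(gel$truth$ladderRows, gel$truth$ladderWeights)
  fit <- fitLadder(bands)
  dual <- ladderCalibration(fit, fit)
  single <- ladderCalibration(fit)
  rowsQ <- c(110, 150, 190)
  for (cf in c(0, 0.3, 1)) {
    expect_equal(pixelToMw(dual, rowsQ, cf), pixelToMw(single, rowsQ),
                 tolerance = 1e-9)
  }

  # genuinely shifted right ladder: colFraction 0 equals the left inversion
  bandsR <- ladderBands(gel$truth$ladderRows + 3, gel$truth$ladderWeights)
  dual2 <- ladderCalibration(fit, fitLadder(bandsR))
  expect_equal(pixelToMw(dual2, rowsQ, 0), pixelToMw(single, rowsQ),
               tolerance = 1e-9)
  # and interpolates between the flank inversions elsewhere
  wl <- pixelToMw(single, 150)
  wr <- pixelToMw(ladderCalibration(fitLadder(bandsR)), 150)
  expect_equal(log10(pixelToMw(dual2, 150, 0.5)),
               (log10(wl) + log10(wr)) / 2, tolerance = 1e-9)
})

test_that("calibration inversion is strictly decreasing in row and round-trips bands", {
  gel <- noiselessGel(seed = 4)
  truth <- gel$truth
  lane <- truth$lanes[1, ]
  fit <- fitLadder(assignLadderWeights(
    detectLadderBands(gel$image, lane$colStart, lane$colEnd),
    truth$ladderWeights))
  cal <- ladderCalibration(fit)
  grid <- seq(min(truth$ladderRows), max(truth$ladderRows), length.out = 50)
  w <- suppressWarnings(pixelToMw(cal, grid))
  expect_true(all(diff(w) < 0))
  back <- suppressWarnings(pixelToMw(cal, truth$ladderRows))
  expect_true(all(abs(back - truth$ladderWeights) / truth$ladderWeights <= 0.02))
})
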