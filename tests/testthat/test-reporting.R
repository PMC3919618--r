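mkFit <- function(mu, sigma, q) {
  new("GaussianFit", a = 1, mu = mu, sigma = sigma, q = q,
      iterations = 5L, converged = TRUE)
}

mkResult <- function(id, mu, sigma, q, muc = NULL, sigmac = NULL, qc = NULL) {
  cf <- if (!is.null(muc)) mkFit(muc, sigmac, qc) else NULL
  sel <- if (!is.null(cf)) cf else mkFit(mu, sigma, q)
  new("LaneResult", laneId = id, rawFit = mkFit(mu, sigma, q),
      correctedFit = cf, maxIntensity = 100,
      rangeLow = sel@mu - 1.18 * sel@sigma,
      rangeHigh = sel@mu + 1.18 * sel@sigma,
      passedQuality = TRUE, qualityThreshold = 0.8, status = "ok")
}

test_that("summaries apply the quality threshold and the 1.18-sigma range rule", {
  res <- list(mkResult("a", 3000, 500, 0.99),
              mkResult("b", 5000, 800, 0.85),
              mkResult("c", 7000, 900, 0.70))
  allPass <- resultsTable(summarizeLanes(res, threshold = 0))
  expect_true(all(allPass$passed_quality))
  onePass <- resultsTable(summarizeLanes(res, threshold = 0.9))
  expect_equal(onePass$passed_quality, c(TRUE, FALSE, FALSE))
  nonePass <- resultsTable(summarizeLanes(res, threshold = 1))
  expect_false(any(nonePass$passed_quality))

  # mu 3000, sigma 500: bar endpoints 2410 and 3590 nt
  expect_equal(allPass$range_low[1], 2410)
  expect_equal(allPass$range_high[1], 3590)
  expect_equal(allPass$lane, c("a", "b", "c"))
})

test_that("sigma_c of 1000 nt reports a 1180 nt bar half-width", {
  r <- mkResult("x", 6000, 1100, 0.9, muc = 5800, sigmac = 1000, qc = 0.95)
  tab <- resultsTable(summarizeLanes(list(r)))
  expect_equal(tab$range_high - (tab$mu_c), 1180)
  expect_equal(tab$mu_c - tab$range_low, 1180)
})

test_that("CSV export round-trips every numeric value exactly", {
  res <- list(mkResult("a", 3000.123456789012, 500.987654321098, 0.991234567),
              mkResult("b", 5000.5, 800.25, 0.85))
  tab <- summarizeLanes(res)
  tf <- withr::local_tempfile(fileext = ".csv")
  exportTable(tab, tf)
  back <- utils::read.csv(tf)
  for (nm in c("mu_r", "sigma_r", "q_r", "range_low", "range_high")) {
    expect_identical(back[[nm]], resultsTable(tab)[[nm]])
  }
  expect_error(exportTable(tab, tf, format = "xlsx"), "not available")
})

test_that("a lane with correction disabled exports empty corrected columns", {
  tab <- summarizeLanes(list(mkResult("a", 3000, 500, 0.99)))
  tf <- withr::local_tempfile(fileext = ".csv")
  exportTable(tab, tf)
  back <- utils::read.csv(tf)
  expect_true(all(c("mu_c", "sigma_c", "q_c") %in% names(back)))
  expect_true(is.na(back$mu_c))
})

test_that("the summary graph renders, honouring hide-failed", {
  res <- list(mkResult("a", 3000, 500, 0.99), mkResult("b", 5000, 800, 0.5))
  tab <- summarizeLanes(res, threshold = 0.9)
  f1 <- withr::local_tempfile(fileext = ".png")
  renderSummaryGraph(tab, f1)
  expect_gt(file.size(f1), 0)
  f2 <- withr::local_tempfile(fileext = ".png")
  renderSummaryGraph(tab, f2, hideFailed = TRUE)
  expect_gt(file.size(f2), 0)
  allFail <- summarizeLanes(res, threshold = 1)
  expect_error(renderSummaryGraph(allFail, f2, hideFailed = TRUE), "no lanes")
})

test_that("the full pipeline recovers multi-lane truth and writes its outputs", {
  mus <- c(3200, 4500, 6000, 9000)
  sl <- data.frame(mu = mus, sigma = 0.15 * mus, signal = 1.2e7,
                   bias = "proportional")
  gel <- generateSyntheticGel(syntheticGelSpec(sampleLanes = sl), seed = 55)
  outDir <- withr::local_tempdir()
  res <- runTrfPipeline(gel$image, ladderWeights = gel$truth$ladderWeights,
                        outDir = outDir)
  tab <- resultsTable(res)
  expect_equal(nrow(tab), 4)
  expect_true(all(abs(tab$mu_c - mus) / mus < 0.05))
  expect_true(file.exists(file.path(outDir, "table.csv")))
  expect_true(file.exists(file.path(outDir, "summary.png")))
  expect_true(file.exists(file.path(outDir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  expect_equal(manifest$correction, "flankMean")
})

test_that("repeated pipeline runs produce byte-identical CSV tables", {
  gel <- makeGel(seed = 66)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeGelImage(gel$image, tf)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  runTrfPipeline(tf, ladderWeights = gel$truth$ladderWeights, outDir = d1)
  runTrfPipeline(tf, ladderWeights = gel$truth$ladderWeights, outDir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "table.csv"))),
                   unname(tools::md5sum(file.path(d2, "table.csv"))))
})

test_that("ladder files in JSON and CSV form drive the pipeline", {
  gel <- makeGel(seed = 67)
  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(gel$truth$ladderWeights, jf)
  cf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(weight = gel$truth$ladderWeights), cf,
                   row.names = FALSE)
  r1 <- resultsTable(runTrfPipeline(gel$image, ladderWeights = jf))
  r2 <- resultsTable(runTrfPipeline(gel$image, ladderWeights = cf))
  expect_identical(r1$mu_c, r2$mu_c)
})
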