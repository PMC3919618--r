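#' Full TRF gel analysis pipeline
#'
#' Runs the complete analysis on one gel scan: image load (or a supplied
#' [GelImage]), optional orientation fixes, automatic lane detection
#' (optionally width-equalized or overridden manually), ladder band
#' detection and weight assignment in the first and last lanes, dual-ladder
#' calibration (or single-ladder on request), per-lane profile extraction,
#' background subtraction, Gaussian smear fitting with probe-intensity
#' correction, and result summary. The pipeline contains no randomness:
#' repeated runs on identical input produce byte-identical CSV output.
#'
#' @param input path to a TIFF scan, or a [GelImage].
#' @param ladderWeights numeric marker weights (nt) present in the ladder
#'   lanes, or the path of a JSON/CSV file holding them (JSON array, or a
#'   CSV whose first column is the weights).
#' @param invert invert signal polarity before analysis (dark bands on a
#'   light background).
#' @param rotate 0, 90, 180 or 270 degrees clockwise.
#' @param crop optional `c(r0, c0, r1, c1)` crop rectangle (0-based,
#'   half-open).
#' @param laneNumberFilter,laneWidthFilter see [detectLanes()].
#' @param constantLanes equalize all lane widths to the narrowest
#'   ([equalizeLaneWidths()]).
#' @param lanes optional manual lane table (data.frame `colStart`,
#'   `colEnd`, `role`), bypassing detection.
#' @param ladderFitModel calibration model id, see [fitLadder()].
#' @param singleLadder `"none"` (use both flanking ladders, the default),
#'   `"first"` or `"last"`.
#' @param background,manualRegionMean,correction,mixWeight,qualityThreshold,allowNegative
#'   per-lane analysis options, see [analyzeLane()].
#' @param outDir optional output directory; when given, writes `table.csv`,
#'   `summary.png` and `manifest.json` (run parameters; the only file
#'   carrying a timestamp).
#' @return a [ResultsTable]; the detected [LaneSet] and
#'   [LadderCalibration] are attached to its metadata.
#' @examples
#' gel <- generateSyntheticGel(syntheticGelSpec(), seed = 7)
#' res <- runTrfPipeline(gel$image, ladderWeights = gel$truth$ladderWeights)
#' resultsTable(res)
#' @export
runTrfPipeline <- function(input, ladderWeights,
                           invert = FALSE, rotate = 0, crop = NULL,
                           laneNumberFilter = 1, laneWidthFilter = 2L,
                           constantLanes = FALSE, lanes = NULL,
                           ladderFitModel = "auto",
                           singleLadder = c("none", "first", "last"),
                           background = "trendline",
                           manualRegionMean = NULL,
                           correction = "flankMean", mixWeight = 0.5,
                           qualityThreshold = 0.8, allowNegative = FALSE,
                           outDir = NULL) {
  singleLadder <- match.arg(singleLadder)
  image <- if (is(input, "GelImage")) input else loadGelImage(input)
  imagePath <- if (is.character(input)) input else "<in-memory GelImage>"
  if (rotate != 0) image <- rotateGel(image, rotate)
  if (invert) image <- invertGel(image)
  if (!is.null(crop)) image <- cropGel(image, crop[1], crop[2], crop[3], crop[4])
  if (is.character(ladderWeights)) ladderWeights <- readLadderFile(ladderWeights)
  ladderWeights <- sort(as.numeric(ladderWeights), decreasing = TRUE)

  if (is.null(lanes)) {
    laneSet <- detectLanes(image, laneNumberFilter, laneWidthFilter)
    if (constantLanes) laneSet <- equalizeLaneWidths(laneSet)
  } else {
    laneSet <- new("LaneSet", lanes = lanes, imageWidth = ncol(gelRaw(image)),
                   laneNumberFilter = laneNumberFilter,
                   laneWidthFilter = as.integer(laneWidthFilter))
  }
  ln <- laneTable(laneSet)
  ladderIdx <- which(ln$role == "ladder")
  sampleIdx <- which(ln$role == "sample")
  if (length(ladderIdx) < 1 || length(sampleIdx) < 1) {
    stop("need at least 2 ladder lanes and 1 sample lane (",
         nrow(ln), " lane(s) detected)")
  }

  fitOne <- function(i) {
    bands <- detectLadderBands(image, ln$colStart[i], ln$colEnd[i])
    fitLadder(assignLadderWeights(bands, ladderWeights), ladderFitModel)
  }
  li <- ladderIdx[1]
  ri <- ladderIdx[length(ladderIdx)]
  cal <- switch(singleLadder,
    first = ladderCalibration(fitOne(li)),
    last = ladderCalibration(fitOne(ri)),
    none = if (ri > li) ladderCalibration(fitOne(li), fitOne(ri))
           else ladderCalibration(fitOne(li))
  )

  centerOf <- function(i) (ln$colStart[i] + ln$colEnd[i]) / 2
  cl <- centerOf(li); cr <- centerOf(ri)
  results <- lapply(sampleIdx, function(i) {
    cf <- if (cal@mode == "dual" && cr > cl) {
      min(1, max(0, (centerOf(i) - cl) / (cr - cl)))
    } else 0
    analyzeLane(image, ln$colStart[i], ln$colEnd[i], cal,
                colFraction = cf, laneId = sprintf("lane%02d", i),
                background = background, manualRegionMean = manualRegionMean,
                correction = correction, mixWeight = mixWeight,
                qualityThreshold = qualityThreshold,
                allowNegative = allowNegative)
  })

  params <- list(
    image = imagePath, ladder_weights = ladderWeights,
    invert = invert, rotate = rotate, crop = crop,
    lane_number_filter = laneNumberFilter,
    lane_width_filter = laneWidthFilter,
    constant_lanes = constantLanes, ladder_fit = ladderFitModel,
    single_ladder = singleLadder, background = background,
    correction = correction, mix_weight = mixWeight,
    quality_threshold = qualityThreshold
  )
  table <- summarizeLanes(results, qualityThreshold, metadata = params)
  table@metadata$laneSet <- laneSet
  table@metadata$calibration <- cal

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    exportTable(table, file.path(outDir, "table.csv"))
    renderSummaryGraph(table, file.path(outDir, "summary.png"))
    manifest <- c(params, list(timestamp = format(Sys.time(), tz = "UTC"),
                               package_version = as.character(utils::packageVersion("telogel"))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  table
}

#' Read a ladder specification file
#'
#' @param path JSON file holding an array of weights (nt), or a CSV whose
#'   first column holds them.
#' @return numeric weights, sorted decreasing.
#' @export
readLadderFile <- function(path) {
  if (!file.exists(path)) stop("ladder file not found: ", path)
  w <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)[[1]]
  }
  sort(as.numeric(w), decreasing = TRUE)
}
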