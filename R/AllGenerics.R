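#' Accessors for gel analysis objects
#'
#' Small accessor generics for the package's S4 classes: raw pixel data and
#' geometry of a [GelImage], the lane table of a [LaneSet], and the summary
#' data.frame of a [ResultsTable].
#'
#' @param object an object of the documented class.
#' @return `gelRaw`: the numeric matrix of raw counts. `gelBitDepth`: 8 or
#'   16. `laneTable`: a data.frame of lane bounds and roles. `resultsTable`:
#'   the per-lane summary data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gelRaw", function(object) standardGeneric("gelRaw"))

#' @rdname accessors
#' @export
setGeneric("gelBitDepth", function(object) standardGeneric("gelBitDepth"))

#' @rdname accessors
#' @export
setGeneric("laneTable", function(object) standardGeneric("laneTable"))

#' @rdname accessors
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @rdname accessors
setMethod("gelRaw", "GelImage", function(object) object@raw)

#' @rdname accessors
setMethod("gelBitDepth", "GelImage", function(object) object@bitDepth)

#' @rdname accessors
setMethod("laneTable", "LaneSet", function(object) object@lanes)

#' @rdname accessors
setMethod("resultsTable", "ResultsTable", function(object) object@table)

setMethod("show", "GelImage", function(object) {
  cat(sprintf(
    "GelImage: %d x %d px, %d-bit%s, counts in [%g, %g]\n",
    nrow(object@raw), ncol(object@raw), object@bitDepth,
    if (object@inverted) ", inverted" else "",
    min(object@raw), max(object@raw)
  ))
})

setMethod("show", "LaneSet", function(object) {
  cat(sprintf("LaneSet: %d lane(s) over %d columns\n",
              nrow(object@lanes), object@imageWidth))
  if (nrow(object@lanes)) print(object@lanes, row.names = FALSE)
})

setMethod("show", "LadderFit", function(object) {
  cat(sprintf(
    "LadderFit (%s): %d bands, d = %d, R2 = %.6f, adj. R2 = %.6f\n",
    object@model, length(object@bands@rows), object@d, object@r2, object@r2adj
  ))
})

setMethod("show", "LadderCalibration", function(object) {
  cat(sprintf("LadderCalibration (%s mode)\n", object@mode))
  show(object@left)
  if (is(object@right, "LadderFit")) show(object@right)
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf(
    "IntensityProfile '%s': %d points, mw %.0f-%.0f nt, background: %s\n",
    object@laneId, length(object@mw),
    if (length(object@mw)) min(object@mw) else NA,
    if (length(object@mw)) max(object@mw) else NA,
    object@backgroundMethod
  ))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: a = %.4g, mu = %.1f nt, sigma = %.1f nt, q = %.4f (%s, %d iter)\n",
    object@a, object@mu, object@sigma, object@q,
    if (object@converged) "converged" else "not converged", object@iterations
  ))
})

setMethod("show", "LaneResult", function(object) {
  cat(sprintf("LaneResult '%s' [%s]\n", object@laneId, object@status))
  cat("  raw:       "); show(object@rawFit)
  if (is(object@correctedFit, "GaussianFit")) {
    cat("  corrected: "); show(object@correctedFit)
  }
  cat(sprintf("  range (mu +/- 1.18 sigma): %.0f-%.0f nt, quality %s\n",
              object@rangeLow, object@rangeHigh,
              if (object@passedQuality) "passed" else "FAILED"))
})

setMethod("show", "ResultsTable", function(object) {
  cat(sprintf("ResultsTable: %d lane(s)\n", nrow(object@table)))
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "SyntheticGelSpec", function(object) {
  cat(sprintf(
    "SyntheticGelSpec: %d x %d px %d-bit, %d sample lane(s) + 2 ladders (%d bands)\n",
    object@rows, object@cols, object@bitDepth,
    nrow(object@sampleLanes), length(object@ladderWeights)
  ))
})
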