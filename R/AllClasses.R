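#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' GelImage: a raw TRF gel scan
#'
#' Container for the raw 2-D intensity array of a terminal restriction
#' fragment (TRF) gel scan. All downstream analysis operates on the raw
#' detector counts held in `raw`; there is no separate display state, so
#' the raw-analysis guarantee holds by construction. Rows increase downward
#' from the wells: a larger row index corresponds to a smaller molecular
#' weight. Signal is assumed bright-on-dark (high counts = probe signal);
#' dark-band scans must be passed through [invertGel()] first.
#'
#' @slot raw numeric matrix of detector counts, `0 <= raw <= 2^bitDepth - 1`.
#' @slot bitDepth integer, 8 or 16.
#' @slot inverted logical, `TRUE` after an odd number of [invertGel()] calls.
#' @slot cropWindow integer vector `c(r0, c0, r1, c1)` in original-image
#'   coordinates (half-open, 0-based rows/cols as supplied to [cropGel()]),
#'   or `NULL` when the image is uncropped.
#' @aliases GelImage
#' @exportClass GelImage
setClass("GelImage",
  representation(
    raw = "matrix",
    bitDepth = "integer",
    inverted = "logical",
    cropWindow = "numericOrNULL"
  ),
  prototype(inverted = FALSE, cropWindow = NULL)
)

setValidity("GelImage", function(object) {
  msgs <- character()
  if (!is.numeric(object@raw)) msgs <- c(msgs, "raw must be numeric")
  if (!(object@bitDepth %in% c(8L, 16L))) {
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  }
  vmax <- 2^object@bitDepth - 1
  if (length(object@raw) && (min(object@raw) < 0 || max(object@raw) > vmax)) {
    msgs <- c(msgs, sprintf("raw values must lie in [0, %d]", vmax))
  }
  if (length(msgs)) msgs else TRUE
})

#' LaneSet: detected gel lanes
#'
#' Ordered, non-overlapping vertical lanes of a gel, each a column interval
#' `[colStart, colEnd)` spanning the full image height. Roles are
#' `"ladder"` (molecular-weight marker), `"sample"` or `"excluded"`.
#'
#' @slot lanes data.frame with columns `colStart`, `colEnd` (integer,
#'   half-open), `role` (character), sorted left to right.
#' @slot laneNumberFilter numeric multiplicative scale applied to the Otsu
#'   threshold during detection.
#' @slot laneWidthFilter integer erosion radius (pixels) applied to the
#'   column profile during detection.
#' @slot imageWidth integer number of image columns the lanes refer to.
#' @aliases LaneSet
#' @exportClass LaneSet
setClass("LaneSet",
  representation(
    lanes = "data.frame",
    laneNumberFilter = "numeric",
    laneWidthFilter = "integer",
    imageWidth = "integer"
  ),
  prototype(laneNumberFilter = 1, laneWidthFilter = 2L)
)

setValidity("LaneSet", function(object) {
  ln <- object@lanes
  msgs <- character()
  if (!all(c("colStart", "colEnd", "role") %in% names(ln))) {
    return("lanes must have columns colStart, colEnd, role")
  }
  if (nrow(ln)) {
    if (any(ln$colStart >= ln$colEnd)) msgs <- c(msgs, "colStart must be < colEnd")
    if (any(ln$colStart < 0) || any(ln$colEnd > object@imageWidth)) {
      msgs <- c(msgs, "lane bounds must lie within the image width")
    }
    if (is.unsorted(ln$colStart, strictly = TRUE)) {
      msgs <- c(msgs, "lanes must be sorted left to right")
    }
    if (nrow(ln) > 1 && any(ln$colStart[-1] < ln$colEnd[-nrow(ln)])) {
      msgs <- c(msgs, "lanes must not overlap")
    }
    if (!all(ln$role %in% c("ladder", "sample", "excluded"))) {
      msgs <- c(msgs, "role must be ladder, sample or excluded")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LadderBands: detected marker bands with assigned weights
#'
#' Band center row positions (pixels, strictly increasing down the gel) of a
#' molecular-weight ladder lane, paired with their assigned weights in nt
#' (strictly decreasing: larger fragments migrate less).
#'
#' @slot rows numeric band center rows (pixels), strictly increasing.
#' @slot weights numeric molecular weights (nt), strictly decreasing.
#' @aliases LadderBands
#' @exportClass LadderBands
setClass("LadderBands",
  representation(rows = "numeric", weights = "numeric")
)

setValidity("LadderBands", function(object) {
  msgs <- character()
  if (length(object@rows) != length(object@weights)) {
    msgs <- c(msgs, "rows and weights must have equal length")
  }
  if (length(object@rows) > 1) {
    if (is.unsorted(object@rows, strictly = TRUE)) {
      msgs <- c(msgs, "rows must be strictly increasing")
    }
    if (is.unsorted(rev(object@weights), strictly = TRUE)) {
      msgs <- c(msgs, "weights must be strictly decreasing with row")
    }
  }
  if (any(object@weights <= 0)) msgs <- c(msgs, "weights must be positive")
  if (length(msgs)) msgs else TRUE
})

#' LadderFit: fitted row-to-molecular-weight calibration
#'
#' A least-squares fit of band row position as a function of log10 molecular
#' weight under one of four monotone models, scored by the coefficient of
#' determination and its adjusted version.
#'
#' @slot model one of `"poly3"`, `"linear"`, `"reciprocal"`, `"spline"`.
#' @slot predictRow function mapping log10(weight) to fitted row.
#' @slot coefficients numeric model parameters (empty for `"spline"`).
#' @slot d integer degrees of freedom of the model (polynomial degree or
#'   equivalent).
#' @slot rss,tss numeric residual and total sum of squares (pixel^2).
#' @slot r2,r2adj numeric coefficient of determination and adjusted version.
#' @slot lwRange numeric length-2 fitted log10-weight range.
#' @slot rowRange numeric length-2 fitted row range.
#' @slot bands the [LadderBands] the fit was made on.
#' @aliases LadderFit
#' @exportClass LadderFit
setClass("LadderFit",
  representation(
    model = "character",
    predictRow = "function",
    coefficients = "numeric",
    d = "integer",
    rss = "numeric",
    tss = "numeric",
    r2 = "numeric",
    r2adj = "numeric",
    lwRange = "numeric",
    rowRange = "numeric",
    bands = "LadderBands"
  )
)

#' LadderCalibration: single- or dual-ladder calibration
#'
#' One fitted ladder, or two flanking ladders used jointly to correct for a
#' horizontal shift in migration across the gel (interpolated in log10-weight
#' space by the lane's horizontal position between the two ladder centers).
#'
#' @slot left [LadderFit] for the left (or only) ladder.
#' @slot right [LadderFit] for the right ladder, or `NULL`.
#' @slot mode `"single"` or `"dual"`.
#' @aliases LadderCalibration
#' @exportClass LadderCalibration
setClass("LadderCalibration",
  representation(left = "LadderFit", right = "ANY", mode = "character")
)

setValidity("LadderCalibration", function(object) {
  if (!(object@mode %in% c("single", "dual"))) return("mode must be single or dual")
  if (object@mode == "dual") {
    if (!is(object@right, "LadderFit")) return("dual mode requires a right LadderFit")
    wl <- object@left@bands@weights
    wr <- object@right@bands@weights
    if (length(wl) != length(wr) || any(wl != wr)) {
      return("dual mode requires identical weight lists in both ladders")
    }
  }
  TRUE
})

#' IntensityProfile: per-lane intensity versus molecular weight
#'
#' Column-averaged lane intensity mapped to molecular weight through a
#' [LadderCalibration], stored sorted by ascending molecular weight. The
#' original image row of each point is retained so that background windows
#' ("first and last 10 pixels of the lane") can be taken in gel-row order.
#'
#' @slot mw numeric molecular weights (nt), strictly increasing.
#' @slot intensity numeric background-subtracted intensities (counts).
#' @slot row numeric image row of each point.
#' @slot laneId character label of the source lane.
#' @slot backgroundMethod `"none"`, `"trendline"`, `"baseline"` or `"manual"`.
#' @aliases IntensityProfile
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(
    mw = "numeric",
    intensity = "numeric",
    row = "numeric",
    laneId = "character",
    backgroundMethod = "character"
  ),
  prototype(laneId = "lane", backgroundMethod = "none")
)

setValidity("IntensityProfile", function(object) {
  msgs <- character()
  n <- length(object@mw)
  if (length(object@intensity) != n || length(object@row) != n) {
    msgs <- c(msgs, "mw, intensity and row must have equal length")
  }
  if (n > 1 && is.unsorted(object@mw, strictly = TRUE)) {
    msgs <- c(msgs, "mw must be strictly increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' GaussianFit: Gaussian model of a TRF smear profile
#'
#' Parameters of `g(x) = a * exp(-(x - mu)^2 / (2 sigma^2))` fitted to an
#' intensity profile by iterative (Levenberg-Marquardt) least squares with a
#' 50-iteration cap, plus the fit quality `q` (coefficient of determination
#' of the fit against the profile it was made on).
#'
#' @slot a numeric amplitude (counts).
#' @slot mu numeric mean telomere length (nt).
#' @slot sigma numeric standard deviation (nt), positive.
#' @slot q numeric fit quality, `<= 1`.
#' @slot iterations integer iterations used (`<= 50`).
#' @slot converged logical, `FALSE` when the iteration cap was reached.
#' @aliases GaussianFit
#' @exportClass GaussianFit
setClass("GaussianFit",
  representation(
    a = "numeric",
    mu = "numeric",
    sigma = "numeric",
    q = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("GaussianFit", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  TRUE
})

#' CorrectedProfile: probe-intensity corrected smear profile
#'
#' An [IntensityProfile] whose falling (high molecular weight) flank has been
#' corrected for probe-binding bias using the Gaussian model of the mirrored
#' rising flank. The rising flank (points up to the intensity maximum) is
#' unchanged by construction.
#'
#' @slot profile the corrected [IntensityProfile].
#' @slot method `"flankMean"` (mean of mirrored-flank Gaussian and original
#'   data) or `"gaussianMixing"` (mix of full-profile and mirrored-flank
#'   Gaussians).
#' @slot gm [GaussianFit] to the mirrored rising flank.
#' @slot go [GaussianFit] to the original full profile (`gaussianMixing`
#'   only), else `NULL`.
#' @slot peakIndex integer index (ascending-mw order) of the intensity
#'   maximum used to split the flanks.
#' @slot mixWeight numeric weight of `gm` in the `gaussianMixing` method.
#' @aliases CorrectedProfile
#' @exportClass CorrectedProfile
setClass("CorrectedProfile",
  representation(
    profile = "IntensityProfile",
    method = "character",
    gm = "GaussianFit",
    go = "ANY",
    peakIndex = "integer",
    mixWeight = "numeric"
  ),
  prototype(go = NULL, mixWeight = 0.5)
)

#' LaneResult: per-lane telomere length statistics
#'
#' Raw and probe-corrected Gaussian fits for one sample lane, with the
#' summary range `mu +/- 1.18 sigma` (covering about 75% of a Gaussian) and
#' the quality-threshold flag.
#'
#' @slot laneId character lane label.
#' @slot rawFit [GaussianFit] to the background-subtracted profile.
#' @slot correctedFit [GaussianFit] to the corrected profile, or `NULL` when
#'   correction was disabled or failed.
#' @slot corrected the [CorrectedProfile], or `NULL`.
#' @slot maxIntensity numeric maximum of the background-subtracted profile.
#' @slot rangeLow,rangeHigh numeric `mu -/+ 1.18 sigma` (nt) of the selected
#'   (corrected when available, else raw) fit.
#' @slot passedQuality logical, selected fit quality at or above threshold.
#' @slot qualityThreshold numeric threshold applied.
#' @slot status `"ok"`, `"raw_only"` (correction unavailable) or `"excluded"`.
#' @aliases LaneResult
#' @exportClass LaneResult
setClass("LaneResult",
  representation(
    laneId = "character",
    rawFit = "ANY",
    correctedFit = "ANY",
    corrected = "ANY",
    maxIntensity = "numeric",
    rangeLow = "numeric",
    rangeHigh = "numeric",
    passedQuality = "logical",
    qualityThreshold = "numeric",
    status = "character"
  ),
  prototype(correctedFit = NULL, corrected = NULL, status = "ok")
)

#' ResultsTable: gel-level summary of lane results
#'
#' One row per analyzed sample lane with mean, standard deviation, fit
#' quality for raw and corrected data, maximum intensity, the
#' `mu +/- 1.18 sigma` range and the quality flag, plus run metadata.
#'
#' @slot table data.frame of per-lane statistics.
#' @slot metadata list of run parameters (image path, ladder weights,
#'   analysis options, package version).
#' @aliases ResultsTable
#' @exportClass ResultsTable
setClass("ResultsTable",
  representation(table = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

#' SyntheticGelSpec: parameters of a simulated TRF gel
#'
#' Full description of a synthetic gel: geometry, migration model, ladder,
#' sample smears (each a Gaussian fragment-length distribution with optional
#' length-proportional probe bias), background and noise. Together with a
#' seed this determines the rendered image exactly.
#'
#' @slot rows,cols integer image size in pixels.
#' @slot bitDepth integer 8 or 16.
#' @slot migration list with `type` (`"loglinear"` or `"cubic"`) and
#'   `coefficients`: for loglinear `c(A, B)` with row = A + B*log10(w); for
#'   cubic `c(c0..c3)` in powers of log10(w). Must be strictly decreasing in
#'   log10(w) over `weightRange`.
#' @slot weightRange numeric length-2 fragment-weight support (nt).
#' @slot ladderWeights numeric marker weights (nt), decreasing.
#' @slot bandSigma numeric ladder band width (pixels).
#' @slot ladderSignal numeric integrated signal per ladder band (counts).
#' @slot sampleLanes data.frame with columns `mu`, `sigma` (nt), `signal`
#'   (total integrated counts) and `bias` (`"none"` or `"proportional"`).
#' @slot laneWidth,gutter integer lane width and inter-lane gap (pixels).
#' @slot background numeric length-2 `c(base, slope)`: counts at row 1 and
#'   counts added per row going down the gel.
#' @slot noiseSd numeric additive Gaussian noise standard deviation (counts).
#' @slot psfSigma numeric point-spread blur along rows (pixels).
#' @aliases SyntheticGelSpec
#' @exportClass SyntheticGelSpec
setClass("SyntheticGelSpec",
  representation(
    rows = "integer",
    cols = "integer",
    bitDepth = "integer",
    migration = "list",
    weightRange = "numeric",
    ladderWeights = "numeric",
    bandSigma = "numeric",
    ladderSignal = "numeric",
    sampleLanes = "data.frame",
    laneWidth = "integer",
    gutter = "integer",
    background = "numeric",
    noiseSd = "numeric",
    psfSigma = "numeric"
  )
)

setValidity("SyntheticGelSpec", function(object) {
  msgs <- character()
  if (!(object@bitDepth %in% c(8L, 16L))) msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (!object@migration$type %in% c("loglinear", "cubic")) {
    msgs <- c(msgs, "migration type must be loglinear or cubic")
  }
  lw <- log10(sort(object@weightRange))
  grid <- seq(lw[1], lw[2], length.out = 200)
  rows <- migrationRow(object@migration, grid)
  if (any(diff(rows) >= 0)) {
    msgs <- c(msgs, "migration model must be strictly decreasing in log10(weight)")
  }
  nLanes <- 2L + nrow(object@sampleLanes)
  need <- nLanes * object@laneWidth + (nLanes + 1L) * object@gutter
  if (object@gutter < 3L) msgs <- c(msgs, "gutters must be at least 3 px")
  if (need > object@cols) {
    msgs <- c(msgs, sprintf("lanes need %d columns, image has %d", need, object@cols))
  }
  if (!all(object@sampleLanes$bias %in% c("none", "proportional"))) {
    msgs <- c(msgs, "bias must be none or proportional")
  }
  if (length(msgs)) msgs else TRUE
})
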