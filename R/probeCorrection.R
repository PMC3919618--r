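#' Split a smear profile at its peak and mirror the rising flank
#'
#' The rising flank is the low molecular weight side of the profile up to
#' the intensity maximum (ties broken toward the lowest weight, keeping the
#' trusted flank maximal). Each rising-flank point at weight `x` is mirrored
#' about the peak to `2 mw_peak - x` with unchanged intensity, producing the
#' symmetric template used for probe-intensity correction.
#'
#' @param profile an [IntensityProfile] (ascending mw).
#' @return list with `rising` (data.frame `mw`, `intensity` of the flank up
#'   to and including the peak), `mirrored` (the reflected points, in
#'   descending order of original mw, i.e. ascending mirrored mw) and
#'   `peakIndex`.
#' @export
splitAndMirror <- function(profile) {
  stopifnot(is(profile, "IntensityProfile"))
  I <- profile@intensity
  peak <- which.max(I)                      # first maximum = lowest mw on ties
  if (peak == 1 || peak == length(I)) {
    stop("degenerate profile: intensity maximum at the profile edge")
  }
  mwPeak <- profile@mw[peak]
  ris <- seq_len(peak)
  list(
    rising = data.frame(mw = profile@mw[ris], intensity = I[ris]),
    mirrored = data.frame(mw = 2 * mwPeak - profile@mw[rev(ris)],
                          intensity = I[rev(ris)]),
    peakIndex = as.integer(peak)
  )
}

fitMirrorGaussian <- function(profile, sm) {
  # fit a free Gaussian to the mirrored rising flank, then reflect the
  # fitted curve back through the mirror axis: the reflected center is
  # 2 mw_peak - mu_hat = the center estimated from the rising-flank data
  # itself, so the (pixel-quantized) choice of mirror axis cancels out of
  # the model used for the falling flank
  x <- sm$mirrored$mw
  I <- sm$mirrored$intensity
  if (max(I) == min(I)) stop("degenerate rising flank")
  fit <- fitGaussianXY(x, I)
  axis <- profile@mw[sm$peakIndex]
  fit@mu <- 2 * axis - fit@mu
  fit
}

#' Probe-intensity correction of a smear profile
#'
#' On denatured Southern blots the probe signal scales with both fragment
#' abundance and fragment length (more binding sites on longer telomeres),
#' inflating the falling (high molecular weight) flank of the smear. The
#' correction models the trusted rising flank: it is mirrored about the
#' peak and fitted with a Gaussian `g_m`. Two correction methods are
#' offered for each falling-flank point `x`:
#' \describe{
#'   \item{`flankMean`}{`corrected(x) = (g_m(x) + original(x)) / 2` — the
#'     mean of the mirrored-flank Gaussian and the original data.}
#'   \item{`gaussianMixing`}{`corrected(x) = w g_m(x) + (1 - w) g_o(x)`
#'     where `g_o` is a Gaussian fitted to the full original profile and
#'     `w = mixWeight` (default 0.5, equal-weight mixing).}
#' }
#' The rising flank is never altered. A profile that is already symmetric
#' about its peak is a fixed point of both methods.
#'
#' @param profile a background-subtracted [IntensityProfile].
#' @param method `"flankMean"` or `"gaussianMixing"`.
#' @param mixWeight weight of `g_m` in `"gaussianMixing"`.
#' @return a [CorrectedProfile].
#' @export
correctProfile <- function(profile, method = c("flankMean", "gaussianMixing"),
                           mixWeight = 0.5) {
  stopifnot(is(profile, "IntensityProfile"))
  method <- match.arg(method)
  sm <- splitAndMirror(profile)
  gm <- fitMirrorGaussian(profile, sm)
  go <- NULL
  x <- profile@mw
  I <- profile@intensity
  fall <- (sm$peakIndex + 1L):length(I)
  if (method == "flankMean") {
    I[fall] <- (gaussAt(gm, x[fall]) + I[fall]) / 2
  } else {
    go <- fitGaussian(profile)
    I[fall] <- mixWeight * gaussAt(gm, x[fall]) +
      (1 - mixWeight) * gaussAt(go, x[fall])
  }
  corr <- profile
  corr@intensity <- I
  new("CorrectedProfile", profile = corr, method = method, gm = gm, go = go,
      peakIndex = sm$peakIndex, mixWeight = mixWeight)
}

#' Analyze one sample lane end to end
#'
#' Composes profile extraction, background subtraction, the raw Gaussian
#' fit, probe-intensity correction with refit, and the summary statistics:
#' the reported range is `mu +/- 1.18 sigma` of the selected fit (corrected
#' when available, else raw), covering about 75% of a Gaussian. A failed
#' correction degrades gracefully to raw-only results (`status`
#' `"raw_only"`); a lane whose raw fit fails yields `status = "excluded"`
#' rather than aborting the gel.
#'
#' @param image a [GelImage].
#' @param colStart,colEnd lane column bounds (0-based, half-open).
#' @param cal a [LadderCalibration].
#' @param colFraction dual-ladder interpolation position of the lane.
#' @param laneId lane label.
#' @param background background method (`"trendline"`, `"baseline"`,
#'   `"manual"`, `"none"`).
#' @param manualRegionMean background counts for `background = "manual"`.
#' @param correction `"flankMean"`, `"gaussianMixing"` or `"none"` (use
#'   `"none"` for native in-gel hybridization blots, whose signal is
#'   length-unbiased).
#' @param mixWeight see [correctProfile()].
#' @param qualityThreshold minimum acceptable fit quality (default 0.8).
#' @param allowNegative see [subtractBackground()].
#' @return a [LaneResult].
#' @export
analyzeLane <- function(image, colStart, colEnd, cal, colFraction = 0,
                        laneId = "lane",
                        background = c("trendline", "baseline", "manual", "none"),
                        manualRegionMean = NULL,
                        correction = c("flankMean", "gaussianMixing", "none"),
                        mixWeight = 0.5, qualityThreshold = 0.8,
                        allowNegative = FALSE) {
  background <- match.arg(background)
  correction <- match.arg(correction)
  failed <- function(msg) {
    new("LaneResult", laneId = laneId, rawFit = NULL,
        maxIntensity = NA_real_, rangeLow = NA_real_, rangeHigh = NA_real_,
        passedQuality = FALSE, qualityThreshold = qualityThreshold,
        status = "excluded")
  }
  prof <- tryCatch(
    extractIntensityProfile(image, colStart, colEnd, cal, colFraction, laneId),
    error = function(e) NULL
  )
  if (is.null(prof)) return(failed("extraction failed"))
  if (background != "none") {
    prof <- tryCatch(
      subtractBackground(prof, background, manualRegionMean, allowNegative),
      error = function(e) NULL
    )
    if (is.null(prof)) return(failed("background subtraction failed"))
  }
  rawFit <- tryCatch(fitGaussian(prof), error = function(e) NULL)
  if (is.null(rawFit)) return(failed("raw fit failed"))

  corrected <- NULL
  correctedFit <- NULL
  status <- "ok"
  if (correction != "none") {
    corrected <- tryCatch(correctProfile(prof, correction, mixWeight),
                          error = function(e) NULL)
    if (is.null(corrected)) {
      status <- "raw_only"
    } else {
      correctedFit <- tryCatch(fitGaussian(corrected@profile),
                               error = function(e) NULL)
      if (is.null(correctedFit)) {
        corrected <- NULL
        status <- "raw_only"
      }
    }
  }
  sel <- if (!is.null(correctedFit)) correctedFit else rawFit
  new("LaneResult", laneId = laneId, rawFit = rawFit,
      correctedFit = correctedFit, corrected = corrected,
      maxIntensity = max(prof@intensity),
      rangeLow = sel@mu - 1.18 * sel@sigma,
      rangeHigh = sel@mu + 1.18 * sel@sigma,
      passedQuality = sel@q >= qualityThreshold,
      qualityThreshold = qualityThreshold, status = status)
}
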