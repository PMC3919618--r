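#' Extract a lane's intensity-versus-molecular-weight profile
#'
#' Averages raw counts across the lane's columns for every image row and
#' maps rows to molecular weight through the calibration. Rows that cannot
#' be mapped to a positive weight (outside the invertible range) are
#' dropped. The result is stored sorted by ascending molecular weight; the
#' source row of each point is retained for row-ordered background windows.
#'
#' @param image a [GelImage].
#' @param colStart,colEnd lane column bounds (0-based, half-open).
#' @param cal a [LadderCalibration].
#' @param colFraction lane center position between the two ladder centers
#'   (dual-mode interpolation; see [pixelToMw()]).
#' @param laneId label stored in the profile.
#' @return an [IntensityProfile] with `backgroundMethod = "none"`.
#' @export
extractIntensityProfile <- function(image, colStart, colEnd, cal,
                                    colFraction = 0, laneId = "lane") {
  stopifnot(is(image, "GelImage"), is(cal, "LadderCalibration"))
  intensity <- rowMeans(image@raw[, (colStart + 1):colEnd, drop = FALSE])
  rows <- seq_along(intensity)
  mw <- suppressWarnings(pixelToMw(cal, rows, colFraction))
  keep <- !is.na(mw) & mw > 0
  mw <- mw[keep]; intensity <- intensity[keep]; rows <- rows[keep]
  o <- order(mw)
  if (anyDuplicated(mw[o])) {
    keep2 <- !duplicated(mw[o])
    o <- o[keep2]
  }
  new("IntensityProfile", mw = mw[o], intensity = intensity[o],
      row = rows[o], laneId = laneId, backgroundMethod = "none")
}

#' Subtract lane background
#'
#' Three subtraction options, all defined on the profile in gel-row order
#' (top of the lane first): `"trendline"` takes the minimum of the first 10
#' and of the last 10 points and subtracts the straight line joining them
#' (removes an intensity gradient along the lane, the recommended option);
#' `"baseline"` subtracts the mean of those two minima everywhere;
#' `"manual"` subtracts a user-supplied background region mean. Negative
#' results are clipped to zero unless `allowNegative = TRUE`.
#'
#' @param profile an [IntensityProfile].
#' @param method `"trendline"`, `"baseline"` or `"manual"`.
#' @param manualRegionMean background counts for `method = "manual"`.
#' @param allowNegative keep negative intensities after subtraction.
#' @return the background-subtracted [IntensityProfile].
#' @export
subtractBackground <- function(profile,
                               method = c("trendline", "baseline", "manual"),
                               manualRegionMean = NULL,
                               allowNegative = FALSE) {
  stopifnot(is(profile, "IntensityProfile"))
  method <- match.arg(method)
  o <- order(profile@row)
  I <- profile@intensity[o]
  n <- length(I)
  if (method %in% c("trendline", "baseline")) {
    if (n < 20) stop("trendline/baseline need at least 20 points (two 10-pixel windows)")
    m1 <- min(I[1:10])
    m2 <- min(I[(n - 9):n])
    bg <- switch(method,
      trendline = m1 + (m2 - m1) * (seq_len(n) - 1) / (n - 1),
      baseline = rep((m1 + m2) / 2, n)
    )
  } else {
    if (is.null(manualRegionMean)) {
      stop("method 'manual' requires manualRegionMean")
    }
    bg <- rep(manualRegionMean, n)
  }
  I <- I - bg
  if (!allowNegative) I <- pmax(I, 0)
  out <- profile
  out@intensity[o] <- I
  out@backgroundMethod <- method
  validObject(out)
  out
}

#' Mean background of a manually selected gel region
#'
#' @param image a [GelImage].
#' @param r0,c0,r1,c1 region rectangle (0-based, half-open).
#' @return mean raw count of the region, for use as `manualRegionMean` in
#'   [subtractBackground()].
#' @export
regionMean <- function(image, r0, c0, r1, c1) {
  stopifnot(is(image, "GelImage"))
  mean(image@raw[(r0 + 1):r1, (c0 + 1):c1])
}

#' Evaluate a fitted Gaussian
#'
#' @param fit a [GaussianFit].
#' @param x numeric molecular weights (nt).
#' @return `a * exp(-(x - mu)^2 / (2 sigma^2))`.
#' @export
gaussAt <- function(fit, x) {
  fit@a * exp(-(x - fit@mu)^2 / (2 * fit@sigma^2))
}

fitGaussianXY <- function(x, I) {
  a0 <- max(I)
  mu0 <- x[which.max(I)]
  half <- x[I >= a0 / 2]
  span <- if (length(half) > 1) diff(range(half)) else 0
  s0 <- if (span > 0) span / 2 else diff(range(x)) / 4
  resFn <- function(p) I - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2))
  out <- minpack.lm::nls.lm(
    par = c(a = a0, mu = mu0, sigma = s0), fn = resFn,
    control = minpack.lm::nls.lm.control(
      maxiter = 50, ftol = 1e-10, ptol = 1e-10, gtol = 0
    )
  )
  p <- out$par
  res <- resFn(p)
  tss <- sum((I - mean(I))^2)
  q <- 1 - sum(res^2) / tss
  new("GaussianFit", a = unname(p[1]), mu = unname(p[2]),
      sigma = abs(unname(p[3])), q = q,
      iterations = as.integer(out$niter),
      converged = out$info %in% 1:4)
}

#' Fit a Gaussian to an intensity profile
#'
#' Fits `g(x) = a exp(-(x - mu)^2 / (2 sigma^2))` to the profile's
#' (molecular weight, intensity) points by Levenberg-Marquardt iterative
#' least squares, capped at 50 iterations. Initialization is deterministic:
#' `a0` = maximum intensity, `mu0` = weight at the maximum, `sigma0` = half
#' the weight span at half maximum (span/4 fallback), so identical input
#' yields identical output. The fit quality `q` is the coefficient of
#' determination of the fitted curve against the profile. Hitting the
#' iteration cap is reported via `converged = FALSE`, not an error.
#'
#' @param profile an [IntensityProfile] with at least 10 points.
#' @return a [GaussianFit].
#' @examples
#' x <- seq(1000, 9000, length.out = 200)
#' p <- new("IntensityProfile", mw = x,
#'          intensity = 2 * exp(-(x - 5000)^2 / (2 * 800^2)), row = rev(x))
#' fitGaussian(p)
#' @export
fitGaussian <- function(profile) {
  stopifnot(is(profile, "IntensityProfile"))
  x <- profile@mw
  I <- profile@intensity
  if (length(x) < 10) stop("need at least 10 points to fit")
  if (max(I) == min(I)) stop("degenerate profile: all intensities equal")
  if (all(I == 0)) stop("degenerate profile: all intensities zero")
  fitGaussianXY(x, I)
}
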