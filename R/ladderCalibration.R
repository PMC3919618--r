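#' Detect bands in a molecular-weight ladder lane
#'
#' Column-averages the lane, smooths the row profile lightly (moving average,
#' window 5), and reports local maxima as band candidates. Each integer
#' maximum is refined to subpixel precision by a 3-point parabolic fit
#' through the smoothed profile. Closely spaced bands merged by blur appear
#' as a single maximum between them; the caller assigns weights and may drop
#' false positives (see [assignLadderWeights()]).
#'
#' @param image a [GelImage].
#' @param colStart,colEnd lane column bounds (0-based, half-open), e.g. one
#'   row of [laneTable()].
#' @param minProminence fraction of the profile's dynamic range a maximum
#'   must rise above the profile minimum to count as a band (default 0.05).
#' @return data.frame with columns `row` (subpixel band center) and
#'   `intensity` (smoothed profile height), sorted by row.
#' @export
detectLadderBands <- function(image, colStart, colEnd, minProminence = 0.05) {
  stopifnot(is(image, "GelImage"))
  prof <- rowMeans(image@raw[, (colStart + 1):colEnd, drop = FALSE])
  n <- length(prof)
  sm <- as.numeric(stats::filter(prof, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- prof[is.na(sm)]
  rng <- max(sm) - min(sm)
  if (rng == 0) stop("flat ladder lane: no bands detectable")
  floorVal <- min(sm) + minProminence * rng
  idx <- which(diff(sign(diff(sm))) < 0) + 1          # strict local maxima
  idx <- idx[sm[idx] >= floorVal]
  if (length(idx) < 3) stop("insufficient ladder bands detected (< 3)")
  # 3-point parabolic subpixel refinement
  rows <- vapply(idx, function(i) {
    if (i <= 1 || i >= n) return(as.numeric(i))
    y0 <- sm[i - 1]; y1 <- sm[i]; y2 <- sm[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(as.numeric(i))
    i - 0.5 * (y2 - y0) / den
  }, numeric(1))
  data.frame(row = rows, intensity = sm[idx])
}

#' Assign molecular weights to detected ladder bands
#'
#' Keeps the `length(weights)` strongest detected bands (dropping weaker
#' false positives), sorts them by row, and pairs them with the supplied
#' weights in decreasing order: the topmost band gets the largest weight.
#'
#' @param bands data.frame from [detectLadderBands()].
#' @param weights numeric ladder weights in nt (any order; sorted
#'   decreasing internally).
#' @return a [LadderBands] object.
#' @export
assignLadderWeights <- function(bands, weights) {
  weights <- sort(as.numeric(weights), decreasing = TRUE)
  if (nrow(bands) < length(weights)) {
    stop(sprintf("detected %d bands but %d weights supplied",
                 nrow(bands), length(weights)))
  }
  keep <- order(bands$intensity, decreasing = TRUE)[seq_along(weights)]
  rows <- sort(bands$row[keep])
  ladderBands(rows, weights)
}

#' Construct a LadderBands object
#'
#' @param rows numeric band center rows (pixels), strictly increasing.
#' @param weights numeric molecular weights (nt), strictly decreasing.
#' @return a [LadderBands].
#' @export
ladderBands <- function(rows, weights) {
  new("LadderBands", rows = as.numeric(rows), weights = as.numeric(weights))
}

#' Coefficient of determination for a calibration fit
#'
#' Computes `rss = sum((y_i - f_i)^2)`, `tss = sum((y_i - mean(y))^2)`,
#' `r2 = 1 - rss/tss` and the adjusted version
#' `r2adj = 1 - (1 - r2) (n - 1) / (n - d - 1)` for a model with `d`
#' degrees of freedom fitted to `n` band positions.
#'
#' @param observed numeric observed band rows (pixels).
#' @param modeled numeric fitted band rows, same length.
#' @param d model degrees of freedom.
#' @return list with `rss`, `tss`, `r2`, `r2adj`.
#' @examples
#' goodnessOfFit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), d = 1)
#' @export
goodnessOfFit <- function(observed, modeled, d) {
  n <- length(observed)
  if (length(modeled) != n) stop("observed and modeled must have equal length")
  if (n < d + 2) stop("need at least d + 2 points")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("degenerate: all observed values equal (tss = 0)")
  rss <- sum((observed - modeled)^2)
  r2 <- 1 - rss / tss
  if (n - d - 1 <= 0) stop("adjusted R2 undefined: n - d - 1 <= 0")
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - d - 1)
  list(rss = rss, tss = tss, r2 = r2, r2adj = r2adj)
}

fitReciprocal <- function(x, y) {
  # row = a + b / (x - c), pole c kept left of the data
  cInit <- min(x) - 1
  resFn <- function(p) y - (p[1] + p[2] / (x - p[3]))
  sl <- stats::coef(stats::lm(y ~ I(1 / (x - cInit))))
  out <- minpack.lm::nls.lm(
    par = c(a = unname(sl[1]), b = unname(sl[2]), c = cInit),
    fn = resFn,
    lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, min(x) - 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  out
}

#' Fit a row-to-molecular-weight calibration model
#'
#' Least-squares fit of band row position as a function of log10(weight)
#' under one of four monotone models: `"poly3"` (cubic polynomial, the
#' default used automatically), `"linear"`, `"reciprocal"`
#' (`row = a + b/(log10 w - c)`) or `"spline"` (cubic smoothing spline).
#' R-squared and adjusted R-squared are computed with [goodnessOfFit()];
#' a warning is raised if the fitted curve is not strictly decreasing in
#' log10(weight) over the band range.
#'
#' @param bands a [LadderBands].
#' @param model `"auto"` (= `"poly3"`), `"poly3"`, `"linear"`,
#'   `"reciprocal"` or `"spline"`.
#' @return a [LadderFit].
#' @export
fitLadder <- function(bands, model = c("auto", "poly3", "linear",
                                       "reciprocal", "spline")) {
  stopifnot(is(bands, "LadderBands"))
  model <- match.arg(model)
  if (model == "auto") model <- "poly3"
  x <- log10(bands@weights)
  y <- bands@rows
  n <- length(y)

  if (model == "poly3") {
    if (n < 5) stop("poly3 needs at least 5 bands (adjusted R2 requires n > d + 1)")
    fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
    cf <- stats::coef(fit)
    pred <- function(lw) cf[1] + cf[2] * lw + cf[3] * lw^2 + cf[4] * lw^3
    d <- 3L
  } else if (model == "linear") {
    if (n < 3) stop("linear needs at least 3 bands")
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    pred <- function(lw) cf[1] + cf[2] * lw
    d <- 1L
  } else if (model == "reciprocal") {
    if (n < 4) stop("reciprocal needs at least 4 bands")
    fit <- fitReciprocal(x, y)
    cf <- fit$par
    pred <- function(lw) cf[1] + cf[2] / (lw - cf[3])
    d <- 2L
  } else { # spline
    if (n < 5) stop("spline needs at least 5 bands")
    fit <- stats::smooth.spline(x, y, keep.data = FALSE)
    pred <- function(lw) stats::predict(fit, lw)$y
    cf <- numeric()
    d <- max(1L, as.integer(round(fit$df)) - 1L)
    if (n - d - 1 <= 0) d <- n - 2L
  }

  modeled <- as.numeric(pred(x))
  gof <- goodnessOfFit(y, modeled, d)
  lwRange <- range(x)
  grid <- seq(lwRange[1], lwRange[2], length.out = 256)
  if (any(diff(pred(grid)) >= 0)) {
    warning("fitted calibration is not strictly monotone over the band range")
  }
  cfNum <- as.numeric(cf)
  force(pred)
  new("LadderFit", model = model, predictRow = function(lw) as.numeric(pred(lw)),
      coefficients = cfNum, d = d, rss = gof$rss, tss = gof$tss,
      r2 = gof$r2, r2adj = gof$r2adj, lwRange = lwRange,
      rowRange = range(y), bands = bands)
}

#' Combine ladder fits into a gel calibration
#'
#' @param left [LadderFit] of the left (or only) ladder.
#' @param right optional [LadderFit] of the right ladder; when given, dual
#'   mode corrects for a migration shift across the gel by interpolating
#'   between the two fits.
#' @return a [LadderCalibration].
#' @export
ladderCalibration <- function(left, right = NULL) {
  mode <- if (is.null(right)) "single" else "dual"
  new("LadderCalibration", left = left, right = right, mode = mode)
}

invertFit <- function(fit, row, extrapolate = 0.5) {
  lo <- fit@lwRange[1] - extrapolate
  hi <- fit@lwRange[2] + extrapolate
  f <- function(lw) fit@predictRow(lw) - row
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Convert pixel rows to molecular weight
#'
#' Numerically inverts the fitted monotone calibration. In dual mode the
#' inversions of both flanking ladders are interpolated linearly in
#' log10-weight space by `colFraction`, the lane center's horizontal
#' position normalized between the two ladder lane centers (0 = left
#' ladder, 1 = right).
#'
#' @param cal a [LadderCalibration].
#' @param row numeric vector of pixel rows.
#' @param colFraction scalar in `[0, 1]` (ignored in single mode).
#' @return numeric molecular weights (nt); `NA` (with a warning) for rows
#'   beyond the invertible range.
#' @export
pixelToMw <- function(cal, row, colFraction = 0) {
  stopifnot(is(cal, "LadderCalibration"))
  outside <- row < cal@left@rowRange[1] | row > cal@left@rowRange[2]
  if (any(outside)) {
    warning(sum(outside), " row(s) outside the calibrated range; extrapolating")
  }
  lwL <- vapply(row, function(r) invertFit(cal@left, r), numeric(1))
  if (cal@mode == "dual") {
    lwR <- vapply(row, function(r) invertFit(cal@right, r), numeric(1))
    lw <- lwL * (1 - colFraction) + lwR * colFraction
  } else {
    lw <- lwL
  }
  10^lw
}
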