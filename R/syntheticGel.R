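# migration model: row position as a function of log10(weight)
migrationRow <- function(migration, lw) {
  cf <- migration$coefficients
  if (migration$type == "loglinear") {
    cf[1] + cf[2] * lw
  } else {
    cf[1] + cf[2] * lw + cf[3] * lw^2 + cf[4] * lw^3
  }
}

# inverse migration: log10(weight) at a given row, by bisection on the
# monotone decreasing model over the spec's weight range
migrationLw <- function(migration, rows, lwRange) {
  vapply(rows, function(r) {
    f <- function(lw) migrationRow(migration, lw) - r
    if (f(lwRange[1]) * f(lwRange[2]) > 0) return(NA_real_)
    stats::uniroot(f, lwRange, tol = 1e-12)$root
  }, numeric(1))
}

#' Describe a synthetic TRF gel
#'
#' Builds a [SyntheticGelSpec] with defaults emulating a typical 16-bit TRF
#' scan: a log-linear migration model `row = 100 (5 - log10 w)` over
#' fragments of 500-50000 nt, two flanking ladders, Col-0-like sample
#' smears (mean 3200 nt, sd 15% of the mean) with length-proportional probe
#' bias, a shallow vertical background gradient and additive Gaussian
#' detector noise.
#'
#' @param rows,cols image size (pixels); `cols = NULL` sizes the image to
#'   the lanes.
#' @param bitDepth 8 or 16.
#' @param migration list `list(type = "loglinear", coefficients = c(A, B))`
#'   with row = A + B log10(w), or
#'   `list(type = "cubic", coefficients = c(c0, c1, c2, c3))`; must be
#'   strictly decreasing in log10(w) over `weightRange`.
#' @param weightRange fragment-weight support (nt).
#' @param ladderWeights marker fragment sizes (nt).
#' @param bandSigma ladder band width (pixels).
#' @param ladderSignal integrated counts per ladder band.
#' @param sampleLanes data.frame with columns `mu`, `sigma` (nt), `signal`
#'   (integrated counts per lane) and `bias` (`"none"` or
#'   `"proportional"`; proportional multiplies abundance by fragment
#'   length, the denatured-Southern probe model).
#' @param laneWidth,gutter lane width and inter-lane gap (pixels).
#' @param background `c(base, slopePerRow)` counts.
#' @param noiseSd additive Gaussian noise sd (counts).
#' @param psfSigma Gaussian point-spread blur along rows (pixels).
#' @return a [SyntheticGelSpec].
#' @export
syntheticGelSpec <- function(rows = 300L, cols = NULL, bitDepth = 16L,
                             migration = list(type = "loglinear",
                                              coefficients = c(500, -100)),
                             weightRange = c(500, 50000),
                             ladderWeights = c(20000, 10000, 8000, 6000, 5000,
                                               4000, 3000, 2500, 2000, 1500,
                                               1000, 750, 500),
                             bandSigma = 1.5, ladderSignal = 2e6,
                             sampleLanes = data.frame(
                               mu = 3200, sigma = 480, signal = 1.2e7,
                               bias = "proportional"),
                             laneWidth = 24L, gutter = 8L,
                             background = c(200, 0.15), noiseSd = 30,
                             psfSigma = 1) {
  nLanes <- 2L + nrow(sampleLanes)
  if (is.null(cols)) {
    cols <- nLanes * as.integer(laneWidth) + (nLanes + 1L) * as.integer(gutter)
  }
  new("SyntheticGelSpec",
      rows = as.integer(rows), cols = as.integer(cols),
      bitDepth = as.integer(bitDepth), migration = migration,
      weightRange = as.numeric(weightRange),
      ladderWeights = sort(as.numeric(ladderWeights), decreasing = TRUE),
      bandSigma = bandSigma, ladderSignal = ladderSignal,
      sampleLanes = sampleLanes, laneWidth = as.integer(laneWidth),
      gutter = as.integer(gutter), background = as.numeric(background),
      noiseSd = noiseSd, psfSigma = psfSigma)
}

gaussianBlur1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, r), x, rep(0, r))
  out <- stats::filter(xp, k, sides = 2)[(r + 1):(r + n)]
  as.numeric(out)
}

#' Generate a ground-truthed synthetic TRF gel
#'
#' Renders the gel described by a [SyntheticGelSpec]: for each sample lane
#' the fragment-length abundance is Gaussian(`mu`, `sigma`); the per-length
#' probe signal is the abundance (bias `"none"`) or abundance times length
#' (bias `"proportional"`); signal mass is mapped to image rows through the
#' migration model with the exact Jacobian `|dw/drow|`, blurred with a
#' small point-spread, and scaled so the integrated (pre-noise, pre-clip)
#' lane signal equals `signal`. Ladder lanes carry Gaussian bands of mass
#' `ladderSignal` at the migration rows of the marker weights. Background
#' gradient and Gaussian noise are then added and the image is quantized to
#' the spec's bit depth with saturation clipping (a warning is raised when
#' more than 1% of pixels saturate). Deterministic for a given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [SyntheticGelSpec].
#' @param seed integer random seed for the noise.
#' @return list with `image` (a [GelImage]), and `truth`: a list carrying
#'   `lanes` (data.frame of 0-based lane bounds and roles), `samples`
#'   (data.frame `mu`, `sigma`, `signal`, `bias`), `ladderRows` (exact band
#'   center rows) and `migration`.
#' @examples
#' gel <- generateSyntheticGel(syntheticGelSpec(), seed = 42)
#' gel$truth$ladderRows
#' @export
generateSyntheticGel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "SyntheticGelSpec"))
  validObject(spec)
  R <- spec@rows; C <- spec@cols
  lwRange <- log10(sort(spec@weightRange))

  # lane layout, 0-based half-open bounds
  nSample <- nrow(spec@sampleLanes)
  nLanes <- nSample + 2L
  starts <- spec@gutter + (seq_len(nLanes) - 1L) * (spec@laneWidth + spec@gutter)
  lanes <- data.frame(
    colStart = as.integer(starts),
    colEnd = as.integer(starts + spec@laneWidth),
    role = c("ladder", rep("sample", nSample), "ladder"),
    stringsAsFactors = FALSE
  )

  img <- matrix(0, nrow = R, ncol = C)
  yy <- seq_len(R)

  # ladder band rows from the migration model
  ladderRows <- migrationRow(spec@migration, log10(spec@ladderWeights))

  renderLadder <- function() {
    col <- numeric(R)
    for (rb in ladderRows) {
      band <- stats::dnorm(yy, mean = rb, sd = spec@bandSigma)
      s <- sum(band)
      if (s > 0) col <- col + band / s * spec@ladderSignal
    }
    col
  }

  renderSample <- function(mu, sigma, signal, bias) {
    lw <- migrationLw(spec@migration, yy, lwRange + c(-1e-9, 1e-9))
    ok <- !is.na(lw)
    w <- 10^lw[ok]
    abundance <- stats::dnorm(w, mean = mu, sd = sigma)
    s <- if (bias == "proportional") abundance * w else abundance
    # the lane profile read against molecular weight reproduces the (probe-
    # biased) abundance curve directly: probe bias is the only distortion
    # the corrector is asked to remove
    col <- numeric(R)
    col[ok] <- s
    col <- gaussianBlur1d(col, spec@psfSigma)
    col[col < 0] <- 0
    tot <- sum(col)
    if (tot <= 0) stop("sample lane renders no signal; check mu against weightRange")
    col / tot * signal
  }

  laneCols <- vector("list", nLanes)
  for (i in seq_len(nLanes)) {
    laneCols[[i]] <- if (lanes$role[i] == "ladder") {
      renderLadder()
    } else {
      sl <- spec@sampleLanes[i - 1L, ]
      renderSample(sl$mu, sl$sigma, sl$signal, sl$bias)
    }
    cols <- (lanes$colStart[i] + 1):lanes$colEnd[i]
    img[, cols] <- img[, cols] + laneCols[[i]] / spec@laneWidth
  }

  # background gradient + noise, under a locally scoped RNG
  img <- img + spec@background[1] + spec@background[2] * (yy - 1)
  if (spec@noiseSd > 0) {
    oldSeed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(oldSeed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", oldSeed, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(R * C, sd = spec@noiseSd), R, C)
  }

  vmax <- 2^spec@bitDepth - 1
  nSat <- sum(img > vmax)
  if (nSat > 0.01 * length(img)) {
    warning(sprintf("%.1f%% of pixels saturate the detector; reduce signal",
                    100 * nSat / length(img)))
  }
  img <- round(pmin(pmax(img, 0), vmax))

  image <- new("GelImage", raw = img, bitDepth = spec@bitDepth)
  truth <- list(
    lanes = lanes,
    samples = spec@sampleLanes,
    ladderRows = ladderRows,
    ladderWeights = spec@ladderWeights,
    migration = spec@migration,
    seed = as.integer(seed)
  )
  list(image = image, truth = truth)
}

#' Write a synthetic gel and its ground-truth sidecar
#'
#' @param gel result of [generateSyntheticGel()].
#' @param path output TIFF path; the truth sidecar is written next to it as
#'   `<path>_truth.json`.
#' @return invisible list of the two paths.
#' @export
writeSyntheticGel <- function(gel, path) {
  writeGelImage(gel$image, path)
  truthPath <- paste0(sub("\\.tiff?$", "", path), "_truth.json")
  jsonlite::write_json(gel$truth, truthPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(image = path, truth = truthPath))
}
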