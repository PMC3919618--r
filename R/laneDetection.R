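#' Otsu threshold of an intensity sample
#'
#' Global image threshold by Otsu's method: the histogram cut maximizing the
#' between-class variance `w0 w1 (mu0 - mu1)^2`. The histogram uses `levels`
#' equal-width bins over `[0, 2^bitDepth - 1]`; for 8-bit data with the
#' default 256 levels each bin is one integer grey level and the returned
#' threshold `t` splits classes as `v <= t` versus `v > t`. Ties are broken
#' toward the lowest threshold. Deterministic.
#'
#' @param values numeric vector or matrix of intensities.
#' @param bitDepth 8 or 16; sets the histogram support.
#' @param levels number of histogram bins (default 256).
#' @return the threshold, on the intensity scale of `values`.
#' @examples
#' otsuThreshold(c(rep(10, 100), rep(200, 100)), bitDepth = 8)
#' @export
otsuThreshold <- function(values, bitDepth = 8L, levels = 256L) {
  v <- as.numeric(values)
  if (!length(v)) stop("empty input")
  if (min(v) == max(v)) stop("constant input: between-class variance undefined")
  vmax <- 2^bitDepth - 1
  binWidth <- (vmax + 1) / levels
  bin <- pmin(floor(v / binWidth), levels - 1)        # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = levels)
  mids <- (seq_len(levels) - 1) * binWidth + binWidth / 2   # bin centers
  # cumulative class statistics for every cut after bin t (t = 1..levels-1)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  n <- w0[levels]
  mTot <- m0[levels]
  t <- seq_len(levels - 1)
  p0 <- w0[t] / n
  p1 <- 1 - p0
  valid <- p0 > 0 & p1 > 0
  mu0 <- m0[t] / w0[t]
  mu1 <- (mTot - m0[t]) / (n - w0[t])
  bcv <- ifelse(valid, p0 * p1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(bcv)                              # first index on ties
  # threshold = top intensity of the last class-0 bin; for 8-bit/256 levels
  # this is the integer grey level t with class split v <= t.
  best * binWidth - 1
}

runningMin <- function(x, radius) {
  if (radius <= 0) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = 2 * radius + 1, FUN = min,
                            partial = TRUE, align = "center"))
}

runningMax <- function(x, radius) {
  if (radius <= 0) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = 2 * radius + 1, FUN = max,
                            partial = TRUE, align = "center"))
}

#' Automatic lane detection
#'
#' Locates vertical gel lanes from the x-projected binary mask: (1) the raw
#' image is thresholded at `laneNumberFilter` times the Otsu threshold; (2)
#' the mask is summed per column; (3) the column profile is eroded with a
#' running minimum of radius `laneWidthFilter` pixels; (4) lane borders are
#' placed at the leftmost minimum of each below-mean valley of the eroded
#' profile; (5) contiguous runs of non-zero, non-border columns become
#' lanes, spanning the full image height. The first and last lanes are
#' assigned the `ladder` role, all others `sample`.
#'
#' @param image a [GelImage] (signal = high counts; see [invertGel()]).
#' @param laneNumberFilter multiplicative scale on the Otsu threshold
#'   (default 1). Raising it removes faint lanes.
#' @param laneWidthFilter erosion radius in pixels (default 2). Raising it
#'   widens the detected inter-lane borders.
#' @return a [LaneSet]; empty (with a warning) when no lane is found.
#' @examples
#' gel <- generateSyntheticGel(syntheticGelSpec(), seed = 1)
#' detectLanes(gel$image)
#' @export
detectLanes <- function(image, laneNumberFilter = 1, laneWidthFilter = 2L) {
  stopifnot(is(image, "GelImage"))
  raw <- image@raw
  if (ncol(raw) < 3) stop("image must be at least 3 columns wide")
  if (laneNumberFilter <= 0) stop("laneNumberFilter must be positive")
  if (laneWidthFilter < 0) stop("laneWidthFilter must be >= 0")
  thr <- laneNumberFilter * otsuThreshold(raw, bitDepth = image@bitDepth)
  mask <- raw > thr
  profile <- colSums(mask)
  rad <- as.integer(laneWidthFilter)
  eroded <- runningMin(profile, rad)
  # morphological opening: erosion suppresses sub-lane-width spikes and
  # deepens borders, dilation restores the support of genuine lanes
  opened <- runningMax(eroded, rad)

  isLane <- opened > 0
  # split touching lanes: a border valley is a below-mean run of the eroded
  # profile that is nonzero throughout (the lanes touch) and flanked by
  # above-mean columns on both sides; the border sits at its leftmost minimum
  m <- mean(eroded)
  below <- eroded < m
  nc <- length(eroded)
  if (any(below)) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1 || i1 == nc) next              # touches the image edge
      if (any(eroded[i0:i1] == 0)) next          # background already separates
      idx <- i0:i1
      border <- idx[which.min(eroded[idx])]      # leftmost minimum
      isLane[border] <- FALSE
    }
  }

  lanes <- data.frame(colStart = integer(), colEnd = integer(),
                      role = character())
  if (any(isLane)) {
    r <- rle(isLane)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    lanes <- data.frame(
      colStart = starts[keep] - 1L,            # 0-based inclusive
      colEnd = ends[keep],                     # exclusive
      role = "sample", stringsAsFactors = FALSE
    )
    if (nrow(lanes) >= 1) lanes$role[1] <- "ladder"
    if (nrow(lanes) >= 2) lanes$role[nrow(lanes)] <- "ladder"
  } else {
    warning("no lanes found at the given filters")
  }
  new("LaneSet", lanes = lanes, laneNumberFilter = laneNumberFilter,
      laneWidthFilter = as.integer(laneWidthFilter),
      imageWidth = ncol(raw))
}

#' Equalize lane widths
#'
#' Shrinks every lane to the width of the narrowest lane, re-centered on its
#' original center (ties rounded toward the left), so integrated intensities
#' are comparable between lanes of the same gel.
#'
#' @param laneSet a [LaneSet] with at least one lane.
#' @return the adjusted [LaneSet].
#' @export
equalizeLaneWidths <- function(laneSet) {
  stopifnot(is(laneSet, "LaneSet"))
  ln <- laneSet@lanes
  if (!nrow(ln)) stop("no lanes to equalize")
  wmin <- min(ln$colEnd - ln$colStart)
  center <- (ln$colStart + ln$colEnd) / 2
  ln$colStart <- as.integer(floor(center - wmin / 2))
  ln$colEnd <- ln$colStart + as.integer(wmin)
  out <- laneSet
  out@lanes <- ln
  validObject(out)
  out
}

#' Manually adjust or insert lanes
#'
#' Applies boundary edits to detected lanes and/or inserts new lanes, then
#' re-sorts and validates. Edits touch column bounds only; lanes always span
#' the full image height.
#'
#' @param laneSet a [LaneSet].
#' @param edits list of `list(index =, colStart =, colEnd =, role =)`;
#'   `role` optional.
#' @param insertions list of `list(colStart =, colEnd =, role =)`.
#' @return the adjusted [LaneSet].
#' @export
adjustLanes <- function(laneSet, edits = list(), insertions = list()) {
  stopifnot(is(laneSet, "LaneSet"))
  ln <- laneSet@lanes
  for (e in edits) {
    i <- e$index
    if (is.null(i) || i < 1 || i > nrow(ln)) stop("edit index out of range")
    if (!is.null(e$colStart)) ln$colStart[i] <- as.integer(e$colStart)
    if (!is.null(e$colEnd)) ln$colEnd[i] <- as.integer(e$colEnd)
    if (!is.null(e$role)) ln$role[i] <- e$role
  }
  for (ins in insertions) {
    ln <- rbind(ln, data.frame(
      colStart = as.integer(ins$colStart), colEnd = as.integer(ins$colEnd),
      role = if (is.null(ins$role)) "sample" else ins$role,
      stringsAsFactors = FALSE
    ))
  }
  ln <- ln[order(ln$colStart), , drop = FALSE]
  rownames(ln) <- NULL
  if (any(bad <- ln$colStart >= ln$colEnd)) {
    stop("inverted bounds for lane at column ", ln$colStart[which(bad)[1]])
  }
  if (any(ln$colStart < 0) || any(ln$colEnd > laneSet@imageWidth)) {
    stop("lane bounds outside image width ", laneSet@imageWidth)
  }
  if (nrow(ln) > 1) {
    ov <- which(ln$colStart[-1] < ln$colEnd[-nrow(ln)])
    if (length(ov)) {
      stop(sprintf("lanes %d and %d overlap after adjustment", ov[1], ov[1] + 1))
    }
  }
  out <- laneSet
  out@lanes <- ln
  validObject(out)
  out
}
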