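#' Summarize lane results into a gel results table
#'
#' One row per sample lane (ladder lanes are never included), with mean,
#' standard deviation and fit quality of the raw and corrected Gaussian
#' fits, the maximum profile intensity, the reported range
#' `mu +/- 1.18 sigma` (nt) of the selected fit, and the quality flag
#' recomputed against `threshold`. Row order follows lane order and the
#' assembly is deterministic.
#'
#' @param results list of [LaneResult] objects.
#' @param threshold fit-quality threshold (default 0.8).
#' @param metadata optional named list of run parameters to attach.
#' @return a [ResultsTable].
#' @export
summarizeLanes <- function(results, threshold = 0.8, metadata = list()) {
  if (!length(results)) stop("no lane results to summarize")
  rows <- lapply(results, function(r) {
    stopifnot(is(r, "LaneResult"))
    rf <- r@rawFit
    cf <- r@correctedFit
    sel <- if (!is.null(cf)) cf else rf
    data.frame(
      lane = r@laneId,
      mu_r = if (!is.null(rf)) rf@mu else NA_real_,
      sigma_r = if (!is.null(rf)) rf@sigma else NA_real_,
      q_r = if (!is.null(rf)) rf@q else NA_real_,
      mu_c = if (!is.null(cf)) cf@mu else NA_real_,
      sigma_c = if (!is.null(cf)) cf@sigma else NA_real_,
      q_c = if (!is.null(cf)) cf@q else NA_real_,
      max_intensity = r@maxIntensity,
      range_low = if (!is.null(sel)) sel@mu - 1.18 * sel@sigma else NA_real_,
      range_high = if (!is.null(sel)) sel@mu + 1.18 * sel@sigma else NA_real_,
      passed_quality = if (!is.null(sel)) sel@q >= threshold else FALSE,
      status = r@status,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  md <- c(metadata, list(quality_threshold = threshold,
                         package_version = as.character(utils::packageVersion("telogel"))))
  new("ResultsTable", table = tab, metadata = md)
}

#' Export a results table
#'
#' Writes the per-lane table as CSV with full double precision (17
#' significant digits), so re-import reproduces every numeric value
#' exactly and repeated runs on identical input are byte-identical.
#'
#' @param table a [ResultsTable].
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
exportTable <- function(table, path, format = c("csv", "xlsx")) {
  stopifnot(is(table, "ResultsTable"))
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx export is not available; use format = 'csv'")
  }
  tab <- table@table
  for (nm in names(tab)) {
    if (is.numeric(tab[[nm]])) {
      tab[[nm]] <- ifelse(is.na(tab[[nm]]), "", sprintf("%.17g", tab[[nm]]))
    }
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render the gel summary graph
#'
#' Draws, for each lane, a vertical bar spanning `mu +/- 1.18 sigma`
#' (covering about 75% of a Gaussian length distribution) on a
#' molecular-weight axis with the mean marked. Lanes whose fit quality
#' falls below the threshold are drawn in red, or omitted entirely with
#' `hideFailed = TRUE`.
#'
#' @param table a [ResultsTable].
#' @param path output file path.
#' @param format `"png"`, `"svg"` or `"tif"`.
#' @param hideFailed omit failed-quality lanes instead of coloring them red.
#' @param width,height device size in pixels (png/tif) or inches (svg).
#' @return `path`, invisibly.
#' @export
renderSummaryGraph <- function(table, path, format = c("png", "svg", "tif"),
                               hideFailed = FALSE, width = 800, height = 600) {
  stopifnot(is(table, "ResultsTable"))
  format <- match.arg(format)
  tab <- table@table
  if (hideFailed) tab <- tab[tab$passed_quality, , drop = FALSE]
  if (!nrow(tab)) stop("no lanes to draw")
  switch(format,
    png = grDevices::png(path, width = width, height = height),
    svg = grDevices::svg(path, width = width / 100, height = height / 100),
    tif = grDevices::tiff(path, width = width, height = height)
  )
  on.exit(grDevices::dev.off(), add = TRUE)
  n <- nrow(tab)
  ylim <- range(c(tab$range_low, tab$range_high), na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = ylim,
                 xlab = "lane", ylab = "molecular weight (nt)",
                 xaxt = "n", main = "Telomere length (mean +/- 1.18 sd)")
  graphics::axis(1, at = seq_len(n), labels = tab$lane, las = 2, cex.axis = 0.8)
  mu <- ifelse(is.na(tab$mu_c), tab$mu_r, tab$mu_c)
  col <- ifelse(tab$passed_quality, "black", "red")
  graphics::segments(seq_len(n), tab$range_low, seq_len(n), tab$range_high,
                     col = col, lwd = 3)
  graphics::points(seq_len(n), mu, pch = 19, col = col, cex = 1.2)
  invisible(path)
}
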