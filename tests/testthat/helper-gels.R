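# Fixture builders shared across tests. Everything is generated in code;
# no binary fixtures are stored.

# a small default gel: two ladders + one Col-0-like sample lane
makeGel <- function(mu = 3200, sigma = 480, bias = "proportional",
                    noiseSd = 30, background = c(200, 0.15), seed = 1,
                    signal = 1.2e7, ...) {
  sl <- data.frame(mu = mu, sigma = sigma, signal = signal, bias = bias)
  generateSyntheticGel(
    syntheticGelSpec(sampleLanes = sl, noiseSd = noiseSd,
                     background = background, ...),
    seed = seed
  )
}

noiselessGel <- function(...) makeGel(noiseSd = 0, background = c(0, 0), ...)

# exact Gaussian intensity profile on an even mw grid
gaussProfile <- function(a = 2, mu = 5000, sigma = 800, n = 200,
                         lim = c(1000, 9000)) {
  x <- seq(lim[1], lim[2], length.out = n)
  new("IntensityProfile", mw = x,
      intensity = a * exp(-(x - mu)^2 / (2 * sigma^2)),
      row = rev(seq_len(n)))
}

# dual calibration built from the default log-linear migration truth
truthCalibration <- function(gel, model = "auto") {
  bands <- ladderBands(gel$truth$ladderRows, gel$truth$ladderWeights)
  fit <- fitLadder(bands, model)
  ladderCalibration(fit, fit)
}

# independent Otsu oracle: explicit per-threshold loop over grey levels
otsuOracle8 <- function(v) {
  best <- -Inf; bestT <- NA
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; bestT <- t }
  }
  bestT
}
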