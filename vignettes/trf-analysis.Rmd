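---
title: "Measuring telomere length from TRF smears with telogel"
author: "telogel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring telomere length from TRF smears with telogel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telogel)
```

## The measurement problem

A terminal restriction fragment (TRF) Southern blot shows telomeric DNA as
a smear: telomere length varies over cells and chromosome ends, so the
probe signal spreads over a range of fragment sizes. Naive summaries of
that smear are biased. Averaging intensity over the whole lane assumes the
distribution is normal without testing it, manual analysis windows couple
the result to the operator and the exposure, and the common probe
correction — dividing intensity by molecular weight — assumes every
possible binding site carries an intact label, which overcorrects long
telomeres badly. `telogel` instead fits an explicit Gaussian model to the
whole smear and corrects probe bias by modelling, not by normalization.

The pipeline is: raw-preserving image import → lane detection → ladder
calibration → per-lane intensity profile → background subtraction →
Gaussian fit → probe-intensity correction and refit → summary table and
graph. Each stage is an exported function operating on an S4 object, so
any stage can be run, inspected or replaced in isolation.

## Raw-data guarantee and image handling

`GelImage` holds nothing but the raw detector counts (8- or 16-bit), so
every downstream number is computed from unmodified data by construction.
The only geometric operations offered are right-angle rotations and
cropping, because arbitrary-angle rotation would interpolate — i.e.
fabricate — raw values. RGB scans are collapsed with the fixed Rec. 601
luminance weights (0.299, 0.587, 0.114); channel-equal images map to the
common channel value exactly. All analysis assumes signal = high counts;
scans with dark bands on a light background must pass through `invertGel()`
once, because the lane-detection mask selects pixels *above* the global
threshold.

## Lane detection

The image is thresholded at `laneNumberFilter ×` the Otsu threshold
(between-class-variance maximization over a 256-bin histogram; ties toward
the lower threshold). The binary mask is summed per column and the column
profile is eroded with a running minimum of radius `laneWidthFilter`
pixels. Lanes are maximal runs of non-zero columns after a morphological
opening (the paired dilation restores the support that erosion removes, so
lane bounds are not biased inward); touching lanes are split at the
leftmost minimum of a below-mean valley that is non-zero throughout and
flanked by above-mean columns. Defaults are `laneNumberFilter = 1`
(dimensionless scale) and `laneWidthFilter = 2` px; raising the former
drops faint lanes, raising the latter merges narrow gaps. The mask sum —
not the raw intensity sum — is projected, so a uniformly brighter exposure
changes detection only through the threshold. Lanes always span the full
image height; `equalizeLaneWidths()` shrinks all lanes to the narrowest
(re-centered, ties toward the left) when integrated intensities must be
comparable, and `adjustLanes()` applies validated manual edits.

## Ladder calibration

Band candidates in the first and last lanes are local maxima of the
lightly smoothed (5-point moving average) row profile, refined to subpixel
precision by a three-point parabolic fit. Subpixel refinement matters: at
the default migration scale of 100 px per decade, a half-pixel rounding
error is already ≈1.2% in weight. The strongest `n` candidates are paired
with the user's `n` ladder weights in decreasing order; merged band pairs
appear as a single maximum and should be resolved by editing the weight
list.

Four monotone models of band row versus `log10(weight)` are available:
cubic polynomial (`poly3`, the default), linear, reciprocal
`row = a + b/(log10 w − c)`, and a cubic smoothing spline. Row is the
response because band position is the measured, noisy quantity. Models are
scored with `R² = 1 − RSS/TSS` and the adjusted version
`1 − (1 − R²)(n−1)/(n−d−1)`, where `d` is the model's degrees of freedom —
hence `poly3` requires at least five bands. Weight lookup inverts the
fitted map numerically (bisection to 1e−10); queries up to half a decade
beyond the fitted range are allowed with a warning. With two flanking
ladders the two inversions are interpolated linearly in log10-weight by the
lane center's horizontal position, which absorbs a uniform migration shift
across the gel; log-space interpolation was chosen because migration is
modelled in log weight throughout.

## Profile extraction, background and the Gaussian fit

A lane's profile is the per-row mean of raw counts across the lane's
columns, mapped to molecular weight and stored in ascending weight order
(the source row is kept). Background options: `trendline` subtracts the
straight line joining the minima of the first and last 10 points in
gel-row order (recommended — it removes a vertical gradient), `baseline`
subtracts the mean of those two minima, `manual` subtracts the mean of a
user-chosen region. Negative intensities are clipped at zero unless
`allowNegative = TRUE`.

The Gaussian `g(x) = a·exp(−(x−µ)²/2σ²)` is fitted by Levenberg–Marquardt
least squares with deterministic initialization (`a₀` = maximum, `µ₀` =
weight at maximum, `σ₀` = half the width at half maximum, span/4 fallback),
a 50-iteration cap and convergence tolerances of 1e−10 on relative RSS and
parameter steps. Hitting the cap sets `converged = FALSE` and is reported,
not raised. The fit quality `q` uses the same coefficient-of-determination
formula as the ladder. Fitting happens in weight space on the row-sampled
(hence log-spaced) points as-is; no Jacobian reweighting is applied, since
the profile is displayed and interpreted against molecular weight. The fit
is fully deterministic, which is what makes repeated pipeline runs
byte-identical.

Amplitude is free rather than area-normalized: it absorbs exposure and
probe activity, which are not of interest, and leaves `µ`, `σ` and `q`
invariant under positive rescaling of the profile (a tested property).

## Probe-intensity correction

On denatured blots, longer telomeres present more probe binding sites, so
the falling (high-weight) flank is inflated relative to fragment
abundance. The rising flank — where binding is closest to proportional and
the profile is smooth — is trusted: points up to the intensity maximum
(ties broken toward lower weight, keeping the trusted flank maximal) are
mirrored about the peak and fitted with a free Gaussian `g_m`, whose
fitted curve is then reflected back through the mirror axis. Reflecting
the *fitted curve* rather than pinning its center to the peak makes the
result independent of which pixel happens to carry the maximum: the
quantized axis cancels in the composition, and `g_m`'s center is the one
the rising-flank data themselves support. Without this, the half-pixel
placement of the peak injects an artifact larger than the correction
itself.

Two corrections are offered for each falling-flank point `x`:
`flankMean` (default) replaces the data with `(g_m(x) + data(x))/2`;
`gaussianMixing` replaces it with `w·g_m(x) + (1−w)·g_o(x)`, where `g_o`
is the Gaussian fit of the full original profile and `w` (`mixWeight`,
default 0.5) gives equal-weight mixing. The equal weight is a documented
choice; no published value exists for it. The corrected profile is
refitted, giving `µ_c, σ_c, Q_c`. Exactly symmetric profiles are fixed
points of both methods, and on length-biased synthetic lanes the two
methods agree on `µ_c` to within a few percent — both tested properties.
No outer error-minimization loop beyond the least-squares refit is
performed. Bimodal or discrete length distributions are deliberately not
deconvolved; they are flagged by low `q` and left to the analyst.

## Reporting

`summarizeLanes()` assembles one row per sample lane with raw and
corrected `µ, σ, q`, the maximum background-subtracted intensity, the
range `µ ± 1.18σ` — the interval holding ≈75% of a Gaussian (2Φ(1.18)−1 =
0.762) — and a pass/fail flag against the quality threshold (default 0.8,
user-adjustable; the "range" column is defined as the same `±1.18σ`
interval as the graph bars). CSV export writes 17 significant digits so
re-import is exact and repeated runs are byte-identical; the run manifest
(the only file with a timestamp) is written separately. The summary graph
draws one vertical bar per lane on a weight axis, red when the lane failed
the threshold, with `hideFailed` to omit such lanes. Spreadsheet-native
(xlsx) export is not provided; the CSV is the canonical machine-readable
output.

## The synthetic gel generator

`generateSyntheticGel()` renders ground-truthed TRF gels so every stage is
testable without scanned blots. Fragment-length abundance in each sample
lane is Gaussian(`mu`, `sigma`); probe bias `"proportional"` multiplies
abundance by length in nt (one binding site per repeat unit — precisely
the bias the corrector must remove), `"none"` models in-gel
hybridization. The per-row signal equals the biased abundance at that
row's weight, so the profile read back against molecular weight reproduces
the biased abundance curve directly; the additional thin-lens-like density
compression that a physical gel adds when signal mass is squeezed into a
shrinking row interval is deliberately not simulated, keeping the probe
bias the single distortion under test. Lanes are blurred with a 1 px
point-spread, scaled to an exact integrated signal, and superimposed on a
linear background gradient with additive Gaussian detector noise, then
quantized with saturation clipping (a warning fires when >1% of pixels
saturate, mirroring the advice to expose within the detector's linear
range).

Defaults model a 16-bit scan with the log-linear migration
`row = 100·(5 − log10 w)` over 500–50000 nt (invertible, and exercisable
by the cubic calibration via the `cubic` option), a 13-band ladder
(20 kb–500 nt, band σ 1.5 px, 2·10⁶ counts per band), 24 px lanes with
8 px gutters, background 200 counts plus 0.15 counts/row, noise σ = 30
counts, and per-lane signal 1.2·10⁷ counts, which puts smear peaks around
30000 counts — a well-exposed scan in the upper linear range. The default
sample lane is Col-0-like: mean 3200 nt with σ = 0.15µ, matching the
short-telomere regime in which TRF correction questions are usually
posed.

What passing tests on these gels shows — and what it does not: the
generator produces clean vertical lanes, Gaussian abundances and additive
Gaussian noise. It does not simulate smiley-gel distortion, bubbles or
blotches, heteroscedastic film response, spatially correlated background,
or skewed/bimodal length distributions. Success on synthetic gels
therefore validates the algorithmic chain (detection, calibration,
fitting, correction, reporting), not robustness to every real-world
artifact; for questionable smears the fit-quality flag and manual lane
tools remain the safeguards.

## Numerical choices and edge cases

* Otsu thresholding uses 256 histogram bins over the full bit-depth range;
  the returned threshold is the top intensity of the lower class, ties
  resolved toward the lower threshold. Constant images are an error (no
  between-class variance).
* Calibration inversion brackets in `log10` weight and is validated for
  strict monotonicity over the fitted range; non-monotone fits warn at fit
  time and error at inversion.
* Gaussian fitting requires ≥10 points and a non-constant profile;
  `σ` is reported as its absolute value (the model is even in `σ`).
* Profiles whose maximum sits at the first or last point have no flank to
  mirror and raise a degenerate-profile error; in the full pipeline a
  failed correction degrades the lane to raw-only results and a failed raw
  fit excludes the lane without aborting the gel.
* Peak ties are broken toward lower molecular weight, background windows
  are taken in gel-row order before weight sorting, and equalized lane
  widths round leftward on ties — all deterministic.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run on 300-row synthetic
gels with one to four sample lanes: 20-seed sweeps for lane-detection
ground truth and for parameter recovery at true means of 3.2, 6 and 12 kb
(σ = 0.15µ, proportional bias, default noise), ten repeated runs for the
byte-identity check, and 50 random 8-bit histograms for the Otsu oracle.
These sizes were chosen as the smallest at which the tested claims are
meaningful across seeds.

## Known limitations

The Gaussian model is the right description only for unimodal,
approximately normal length distributions; `q` flags departures but the
package will not decompose mixtures. The mirror correction presumes the
rising flank is unbiased; protocols where short fragments are
preferentially lost violate that premise. Dual-ladder interpolation is
linear in log weight and corrects a horizontal shift, not curved
("smiley") migration — internal markers are the better remedy there. The
four calibration models are standard electrophoresis families, not
physical mobility models.
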