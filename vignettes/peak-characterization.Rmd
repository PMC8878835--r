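---
title: "Characterizing and filtering picked LC-MS peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and filtering picked LC-MS peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakchar)
```

## The problem

Automated peak picking in untargeted LC-MS metabolomics (centWave and
relatives) is deliberately tuned to miss as little as possible, and
therefore reports many entries that are not chromatographic peaks at all:
noise excursions, baseline ripple from the LC pump strokes, and fragments
of real peaks. These false entries degrade retention alignment and
correspondence and waste analyst time downstream. `peakchar` goes back to
the raw data for every picked peak, measures the quality metrics an
analytical chemist would read off a chromatogram — signal-to-noise ratio,
area, widths, tailing — and removes entries that fail configurable
thresholds.

## The procedure

For each row of the picked-peak table:

1. **Ion trace extraction.** The extracted ion chromatogram (EIC) for the
   peak's m/z is retrieved from the raw centroided MS1 data with a
   relative m/z window of `ppm` parts per million (default 50, matching
   the usual picking tolerance). Intensities of all centroids inside the
   window are **summed** per scan; scans without a matching centroid
   contribute explicit zeros so the trace is gap-free on the scan grid.
   The trace is extracted over an extended window `[rtmin - k*w, rtmax +
   k*w]` with `w = rtmax - rtmin` and `k = 2`: the picker's own bounds
   contain almost no baseline, and both the noise estimate and the
   baseline expansion need non-peak scans on each side. Both choices
   (summing, `k`) are configurable.

2. **Smoothing and derivatives.** The trace is smoothed with a
   Savitzky-Golay filter (polynomial order 3) applied `smooth_times = 2`
   times, or optionally a moving mean. The window is chosen per peak as
   the odd integer nearest to the peak's sigma in scans (estimated as
   `(rtmax - rtmin)/4`, i.e. reading the picker's bounds as roughly
   +/- 2 sigma), clamped to `[min_w, max_w] = [5, 21]`. First and second
   derivatives are computed from the final smoothed trace with SG
   derivative coefficient passes, in per-scan units — only relative
   comparisons are made with them, so this convention is safe on
   non-uniform scan grids.

3. **Apex detection.** Peak apices are negative local minima of the
   second derivative cradled by inflection points (zero-crossings of
   `d2`). A robust noise gate suppresses wiggle candidates: a minimum
   qualifies only if `|d2| > g * MAD(d2)/0.6745` with `g = 2`
   (configurable; 0 disables). The apex is refined to the crest of the
   smoothed intensity between the inflections when that crest is strictly
   interior; on monotone flanks (shoulder members) the `d2` minimum
   itself is kept.

4. **Baseline expansion.** Starting from the inflection points, the
   baseline anchors move outward one scan at a time while the slope
   difference between the tangent at each anchor and the current
   baseline chord exceeds a threshold expressed as a percentage of the
   initial difference: `liftoff` (default 0 %) for the front, `touchdown`
   (default 0.5 %) for the tail. Sides advance alternately, the side with
   the larger normalized excess first, which makes the result independent
   of front/tail labeling for symmetric peaks. A side whose initial slope
   difference is not positive stops immediately (a percentage of a
   non-positive quantity is meaningless); a side stops at the trace edge
   (`edge` boundary) or where it meets a neighbouring candidate's
   inflection region, where cluster handling takes over.

5. **Cluster resolution.** Peaks with overlapping expanded bounds form
   co-eluting clusters (transitive closure of interval overlap; the
   cluster baseline is drawn between the union extremes). Between each
   adjacent pair of member apices the boundary is classified by the
   curvature first: if the second derivative never reaches zero between
   the two `d2` minima the pair is *rounded* and separated at the
   intervening `d2` maximum; with a zero-crossing pair present, a local
   minimum of the smoothed intensity strictly between the apices makes a
   *valley* boundary at the lowest point, otherwise the pair is a
   *shoulder* separated at the `d2` maximum. Checking curvature before
   valleys matters in practice: a one-scan noise dip would otherwise
   promote a rounded pair — two curvature lobes of one physical peak — to
   an unmergeable valley pair and split the peak in half. Shoulder and
   rounded members whose smaller apex sits fewer than `min_shoulder_pts`
   / `min_rounded_pts` scans (default 3) from the bounding `d2` maximum
   are merged into the taller member, which inherits the union of the
   bounds; a picked peak that matches a merged-away candidate is scored
   on the surviving member and flagged `merged`.

6. **Characteristics.** With the baseline drawn between the bound
   anchors: height `h` is the baseline-corrected smoothed apex; the area
   is the trapezoid integral of the baseline-corrected **raw** trace
   between the bounds (negative values clipped to zero — noise below the
   baseline should not subtract signal); the noise `N` is the mean
   absolute peak-to-peak difference between adjacent alternating local
   extrema of the raw intensities over all non-peak scans (with a robust
   MAD-of-differences fallback, flagged, when fewer than two extrema
   exist); `S/N = 2h/N` following the European Pharmacopoeia convention;
   widths at 50 % (FWHM), 10 % and 5 % of `h` are located on the
   smoothed baseline-corrected trace by linear interpolation, walking
   outward from the apex and capped (flagged) at the bounds; the tailing
   factor is `b/a`, the ratio of tail to front half-widths at 10 %
   height (the 5 % half-widths are reported as informational columns).
   Fractional-height crossings are measured on the smoothed trace for
   noise robustness; the area is measured on the raw trace for intensity
   fidelity.

7. **Filtering.** A peak is removed when it lacks the characteristic
   second-derivative signature (`no_peak_signature`, including unmatched
   or non-positive-height entries), or when any enabled threshold is
   violated: fewer than `min_inf_width = 3` scans between inflections,
   fewer than `min_pts = 7` scans between bounds, `S/N < min_sn = 10`,
   area `< min_intensity = 2000` (note: despite the name this applies to
   the trapezoid **area**), tailing factor outside `interval_tf`
   (disabled by default), FWHM below `min_fwhm` (disabled by default).
   Comparisons are strict — a peak exactly at a minimum is kept — and all
   violated criteria are recorded, not just the first, so per-criterion
   removal statistics are meaningful.

Optionally (`deconvolve = TRUE`), each multi-member cluster is refit as a
sum of exponentially modified Gaussians (EMG) by Levenberg-Marquardt
least squares, initialized from the detected apices and inflection
widths. This refines the characteristics of strongly overlapped peaks
but is slow and never alters filter decisions, so it is off by default.

## Numerical choices

* **Edge handling.** Near the trace ends the SG window shrinks
  symmetrically (minimum 3 points) instead of padding — padding would
  fabricate intensity exactly where baseline expansion reads values. The
  derivative estimates of the outermost three scans come from 3-point
  windows and are excluded from candidate seeding.
* **Derivative support.** The second-derivative pass uses a wider window
  (`2w - 1`, capped at `max_w`) than the value pass. Double
  differentiation amplifies high-frequency noise steeply; with the
  narrow value window the `d2` noise floor can exceed the curvature of
  genuine low-S/N peaks, while widening the *value* window would clip
  peak heights. The first derivative, which supplies baseline-expansion
  tangents, keeps the smoothing window so tail slopes stay local.
* **Degenerate inputs.** Candidates whose inflections are adjacent
  return their inflections as bounds, flagged; traces shorter than
  `min_w` are a per-peak error (logged and flagged, never fatal to the
  run); a zero noise estimate flags the S/N as infinite rather than
  dividing by zero; float jitter on flat stretches is kept out of
  detection by an absolute curvature floor relative to the intensity
  scale.
* **Rounded pairs at the detection stage.** A `d2` minimum whose flank
  lacks a zero-crossing before the next qualifying minimum takes the
  intervening `d2` local maximum as its anchor (tagged `d2max`), so the
  members of rounded pairs survive detection and can be merged or
  separated downstream.

## The synthetic benchmark

`gen_trace()` and `gen_benchmark()` generate chromatograms with known
ground truth: EMG-shaped peaks (`tau = 0` degenerates to a Gaussian by an
explicit branch; the area is `amplitude * sigma * sqrt(2*pi)` for every
`tau`) over a noise model with constant baseline, slow linear drift,
periodic low-amplitude ripple emulating pump-stroke artifacts, and white
Gaussian noise, clipped at zero.

The benchmark run emulates the situation the filter is built for: 100
true peaks whose S/N is stratified over {15, 30, 60, 120} — each
channel's amplitude is calibrated against the realized noise of that
channel, measured with the same alternating-extrema rule the estimator
uses, so the stated S/N is true by construction — and 100 false
peak-table entries pointing at ripple crests (ripple amplitude 100
counts, period 25 s) and white-noise excursions, all with true S/N < 5.
The conditions are: scan spacing 0.5 s over a 600 s run, peak sigma
uniform in 2.5-5 s, half the true peaks tailed with `tau` up to
1.2 sigma, white noise sd 50 counts on a baseline of 200 counts, drift
within +/- 0.1 counts/s, ripple amplitude 30 counts on true channels.
Every entry lives on its own m/z channel 2 Da apart, so the mzML path
(write, read, ppm extraction) is exercised end to end.

What the generator does **not** emulate — and what green tests therefore
do not certify on real data: Poisson counting statistics and
heteroscedastic detector noise, isotope/adduct structure within the m/z
window, retention drift between samples, and detector saturation. The
benchmark's classification scores (TPR/TNR around 0.97-1.0 at the default
thresholds) are upper bounds that real, messier data will not reach.

Test problem sizes were chosen to keep the full suite fast while leaving
the conclusions unchanged: the benchmark used by the test suite and the
acceptance script is 100 true + 100 false channels on a 1201-scan grid;
the baseline-expansion oracle runs 50 randomized noiseless cases;
deconvolution recovery uses single- and two-component fits on ~400-600
scan traces.

## Known limitations

* The smoothing window tracks the picker's width estimate; grossly wrong
  `rtmin`/`rtmax` from the picker propagate into a mis-sized window.
* Heavily tailed peaks at the lowest S/N stratum can fall below the
  second-derivative noise gate (their apex curvature is genuinely small);
  they are removed as lacking a peak signature. Lowering `d2_gate` trades
  this against noise candidates.
* Co-elution closer than about two sigma produces a single curvature
  lobe and is treated — intentionally — as one peak; deconvolution cannot
  recover components that never appear as distinct `d2` minima.
* Cluster members share the linear cluster baseline; a strongly sloping
  true baseline under a wide cluster biases member areas.
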