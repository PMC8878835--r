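Package: peakchar
Title: Characterization and Quality Filtering of Chromatographic Peaks in LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes chromatographic peaks reported by peak-picking
    software (e.g. the XCMS chromPeaks table) directly against the raw
    centroided MS1 data. For each picked peak the extracted ion chromatogram
    is retrieved at a user ppm tolerance, smoothed with a Savitzky-Golay (or
    moving-mean) filter, and all peak apices are located as negative local
    minima of the second derivative cradled by inflection points. Peak
    boundaries are found by iterative baseline expansion from the inflection
    points under liftoff/touchdown slope-difference thresholds; co-eluting
    clusters with overlapping bounds are resolved into valley, shoulder and
    rounded boundaries, optionally refined by exponentially-modified-Gaussian
    deconvolution. Analytical quality metrics (noise, signal-to-noise ratio
    2h/N, trapezoid area, base/5%/10% widths, FWHM, tailing factor) are
    computed per peak and used to filter low-quality peaks by configurable
    rules. Includes a synthetic chromatogram and benchmark generator with
    known ground truth and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    signal,
    pracma,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
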