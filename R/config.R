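#' Smoother configuration
#'
#' Settings for the trace smoother and its derivative filters. Defaults are
#' the package defaults for untargeted LC-MS data: a Savitzky-Golay filter
#' applied twice, with the window size chosen automatically per peak from the
#' picked peak's width (see [auto_window()]) and clamped to `[min_w, max_w]`.
#'
#' @param method Smoothing method, `"savgol"` (Savitzky-Golay, default) or
#'   `"mean"` (moving window mean).
#' @param times Number of times the smoother is applied (default 2).
#' @param win Fixed odd window size in scans, or `NULL` to determine it
#'   automatically from the peak width.
#' @param min_w Minimum smoothing window (odd scans, default 5).
#' @param max_w Maximum smoothing window (odd scans, default 21).
#' @param max_sigma Cap (in scans) on the peak-width sigma estimate used for
#'   automatic window selection, or `NULL` for no cap.
#' @return A list of class `smoother_config`.
#' @export
smoother_config <- function(method = c("savgol", "mean"), times = 2L,
                            win = NULL, min_w = 5L, max_w = 21L,
                            max_sigma = NULL) {
  method <- match.arg(method)
  times <- as.integer(times)
  if (times < 1L) stop("smooth_times must be >= 1")
  min_w <- as.integer(min_w); max_w <- as.integer(max_w)
  if (min_w %% 2L == 0L || max_w %% 2L == 0L)
    stop("min_w and max_w must be odd")
  if (min_w > max_w) stop("min_w must be <= max_w")
  if (!is.null(win)) {
    win <- as.integer(win)
    if (win %% 2L == 0L) stop("smooth_win must be odd")
  }
  structure(list(method = method, times = times, win = win,
                 min_w = min_w, max_w = max_w, max_sigma = max_sigma),
            class = "smoother_config")
}

#' Baseline expansion configuration
#'
#' Termination thresholds for the iterative baseline expansion, given as
#' percent of the slope differences at the initial inflection-point baseline.
#' `liftoff` applies to the peak front, `touchdown` to the tail.
#'
#' @param liftoff Front threshold in percent (default 0).
#' @param touchdown Tail threshold in percent (default 0.5).
#' @return A list of class `expansion_config`.
#' @export
expansion_config <- function(liftoff = 0, touchdown = 0.5) {
  if (liftoff < 0 || liftoff > 100 || touchdown < 0 || touchdown > 100)
    stop("liftoff and touchdown must be in [0, 100] percent")
  structure(list(liftoff = liftoff, touchdown = touchdown),
            class = "expansion_config")
}

#' Peak filter configuration
#'
#' Thresholds used to decide which characterized peaks to keep. Comparisons
#' are strict: a peak is removed when a metric is strictly below its minimum
#' (so a peak with S/N exactly `min_sn` is kept). `min_intensity` applies to
#' the trapezoid peak area computed here, not the apex height, despite the
#' parameter name.
#'
#' @param ppm m/z tolerance (parts per million) for ion trace extraction
#'   (default 50).
#' @param min_pts Minimum number of scans between the peak bounds (default 7).
#' @param min_inf_width Minimum number of scans between the second-derivative
#'   inflection points (default 3).
#' @param min_sn Minimum signal-to-noise ratio 2h/N (default 10).
#' @param min_intensity Minimum peak area in counts*seconds (default 2000).
#' @param min_shoulder_pts Minimum scans between the bounding second-derivative
#'   maximum and the apex of the smaller member of a shoulder pair; pairs below
#'   this are merged (default 3).
#' @param min_rounded_pts As `min_shoulder_pts` for rounded pairs (default 3).
#' @param interval_tf Numeric `c(lo, hi)` allowed tailing-factor interval, or
#'   `NULL` (default) to disable the tailing-factor filter.
#' @param min_fwhm Minimum full width at half maximum in seconds, or `NULL`
#'   (default) to disable.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(ppm = 50, min_pts = 7L, min_inf_width = 3L,
                          min_sn = 10, min_intensity = 2000,
                          min_shoulder_pts = 3L, min_rounded_pts = 3L,
                          interval_tf = NULL, min_fwhm = NULL) {
  if (!is.null(interval_tf)) {
    if (length(interval_tf) != 2L || interval_tf[1] >= interval_tf[2])
      stop("interval_tf must be c(lo, hi) with lo < hi")
  }
  stopifnot(ppm > 0, min_pts >= 0, min_inf_width >= 0, min_sn >= 0,
            min_intensity >= 0, min_shoulder_pts >= 0, min_rounded_pts >= 0)
  structure(list(ppm = ppm, min_pts = as.integer(min_pts),
                 min_inf_width = as.integer(min_inf_width), min_sn = min_sn,
                 min_intensity = min_intensity,
                 min_shoulder_pts = as.integer(min_shoulder_pts),
                 min_rounded_pts = as.integer(min_rounded_pts),
                 interval_tf = interval_tf, min_fwhm = min_fwhm),
            class = "filter_config")
}

#' Full pipeline configuration
#'
#' Bundles the smoother, baseline-expansion and filter settings together with
#' the trace-extraction parameters. All fields default to the package
#' defaults, so `run_config()` with no arguments is a complete, valid
#' configuration.
#'
#' @param smoother A [smoother_config()].
#' @param expansion An [expansion_config()].
#' @param filters A [filter_config()].
#' @param eic_k Extension factor for the ion trace window: the trace is
#'   extracted over `[rtmin - k*w, rtmax + k*w]` with `w = rtmax - rtmin`
#'   (default 2), so that non-peak scans are available for noise estimation
#'   and neighbouring peaks are visible.
#' @param d2_gate Robust-scale gate `g` for second-derivative minima: a
#'   candidate apex requires `|d2| > g * MAD(d2)/0.6745`. `0` disables
#'   (default 2).
#' @param deconvolve Logical; fit an EMG mixture to each multi-peak cluster
#'   (informational only, default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(smoother = smoother_config(),
                       expansion = expansion_config(),
                       filters = filter_config(),
                       eic_k = 2, d2_gate = 2, deconvolve = FALSE) {
  stopifnot(inherits(smoother, "smoother_config"),
            inherits(expansion, "expansion_config"),
            inherits(filters, "filter_config"),
            eic_k >= 0, d2_gate >= 0)
  structure(list(smoother = smoother, expansion = expansion,
                 filters = filters, eic_k = eic_k, d2_gate = d2_gate,
                 deconvolve = isTRUE(deconvolve)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a flat YAML file whose keys use the standard parameter names
#' (`ppm`, `min_pts`, `min_inf_width`, `min_sn`, `min_intensity`,
#' `min_shoulder_pts`, `min_rounded_pts`, `interval_tf`, `min_fwhm`,
#' `min_w`, `max_w`, `smooth_method`, `smooth_times`, `smooth_win`,
#' `max_sigma`, `liftoff`, `touchdown`, plus `eic_k`, `d2_gate`,
#' `deconvolve`). Keys not present keep their defaults.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(vals)) vals <- list()
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  sm <- smoother_config(
    method = pick("smooth_method", "savgol"),
    times = pick("smooth_times", 2L),
    win = vals[["smooth_win"]],
    min_w = pick("min_w", 5L),
    max_w = pick("max_w", 21L),
    max_sigma = vals[["max_sigma"]])
  ex <- expansion_config(liftoff = pick("liftoff", 0),
                         touchdown = pick("touchdown", 0.5))
  fl <- filter_config(
    ppm = pick("ppm", 50),
    min_pts = pick("min_pts", 7L),
    min_inf_width = pick("min_inf_width", 3L),
    min_sn = pick("min_sn", 10),
    min_intensity = pick("min_intensity", 2000),
    min_shoulder_pts = pick("min_shoulder_pts", 3L),
    min_rounded_pts = pick("min_rounded_pts", 3L),
    interval_tf = vals[["interval_tf"]],
    min_fwhm = vals[["min_fwhm"]])
  run_config(smoother = sm, expansion = ex, filters = fl,
             eic_k = pick("eic_k", 2), d2_gate = pick("d2_gate", 2),
             deconvolve = pick("deconvolve", FALSE))
}
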