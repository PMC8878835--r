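# Savitzky-Golay coefficients for the m-th derivative at the window center.
# offsets -h..h, polynomial order p (p >= m required). Units: per scan.
sg_coef <- function(half, p = 3L, m = 0L) {
  off <- seq.int(-half, half)
  p <- min(p, length(off) - 1L)
  if (p < m) stop("polynomial order too low for derivative order")
  X <- outer(off, 0:p, `^`)
  C <- solve(crossprod(X), t(X))
  factorial(m) * C[m + 1L, ]
}

# Apply an SG filter of derivative order m with window w = 2*half+1,
# shrinking the window symmetrically near the trace ends (minimum 3 points).
# At the two end points (no symmetric 3-point window) the value is copied
# from the nearest interior estimate for derivatives, or left as-is for m=0.
sg_apply <- function(y, w, p = 3L, m = 0L) {
  n <- length(y)
  if (w > n) w <- n - (1L - n %% 2L)  # largest odd window fitting the trace
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  if (n >= w) {
    interior <- (half + 1L):(n - half)
    co <- sg_coef(half, p, m)
    conv <- stats::filter(y, rev(co), method = "convolution", sides = 2L)
    out[interior] <- conv[interior]
  }
  # shrunk windows towards the edges
  for (i in seq_len(min(half, n))) {
    h <- i - 1L
    j <- n - i + 1L
    if (h >= 1L) {
      ce <- sg_coef(h, p, m)
      out[i] <- sum(ce * y[(i - h):(i + h)])
      out[j] <- sum(ce * y[(j - h):(j + h)])
    } else {
      out[i] <- if (m == 0L) y[i] else NA_real_
      out[j] <- if (m == 0L) y[j] else NA_real_
    }
  }
  if (m > 0L) {
    # end points: replicate nearest defined estimate
    idx <- which(is.na(out))
    for (i in idx) out[i] <- if (i <= half) out[half + 1L] else out[n - half]
    if (n >= 3L) {
      out[1L] <- out[2L]
      out[n] <- out[n - 1L]
    }
  }
  out
}

mean_apply <- function(y, w) {
  n <- length(y)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, y))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

central_diff <- function(y, m = 1L) {
  n <- length(y)
  if (m == 1L) {
    d <- numeric(n)
    if (n >= 3L) d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / 2
    d[1L] <- y[2L] - y[1L]
    d[n] <- y[n] - y[n - 1L]
    d
  } else {
    d <- numeric(n)
    if (n >= 3L) d[2:(n - 1L)] <- y[3:n] - 2 * y[2:(n - 1L)] + y[1:(n - 2L)]
    d[1L] <- d[2L]
    d[n] <- d[n - 1L]
    d
  }
}

#' Automatic smoothing window selection
#'
#' Chooses the Savitzky-Golay/moving-mean window as the odd integer nearest
#' to the peak-width sigma expressed in scans, clamped to
#' `[cfg$min_w, cfg$max_w]`. When the configuration sets `max_sigma`, the
#' sigma estimate is capped there first; when it sets a fixed `win`, that
#' window is returned unchanged.
#'
#' @param sigma_scans Peak sigma estimate in scans (> 0). For an XCMS peak
#'   this is typically `(rtmax - rtmin) / 4` converted to scans.
#' @param cfg A [smoother_config()].
#' @return An odd integer window size.
#' @export
auto_window <- function(sigma_scans, cfg = smoother_config()) {
  if (!is.null(cfg$win)) return(cfg$win)
  stopifnot(sigma_scans > 0)
  if (!is.null(cfg$max_sigma)) sigma_scans <- min(sigma_scans, cfg$max_sigma)
  w <- 2L * as.integer(round((sigma_scans - 1) / 2)) + 1L  # nearest odd
  max(cfg$min_w, min(cfg$max_w, w))
}

#' Smooth an ion trace and compute its derivatives
#'
#' Applies the configured smoother `times` times to the raw intensities and
#' computes first and second derivatives of the final smoothed trace: for
#' the Savitzky-Golay method via one extra pass with the polynomial
#' derivative coefficients, for the moving mean via central finite
#' differences. Derivatives are in per-scan units (counts/scan and
#' counts/scan^2); all downstream derivative logic uses only relative
#' comparisons, so this convention is safe on non-uniform rt grids.
#' Negative smoothed intensities are clamped to zero in the reported `y`
#' only; derivatives are computed from the unclamped values.
#'
#' @param trace An `IonTrace`.
#' @param cfg A [smoother_config()].
#' @param window Odd window size in scans; when `NULL`, taken from
#'   `cfg$win` or defaulted to `cfg$min_w`.
#' @return A `SmoothedTrace`: list with `rt`, `y_raw`, `y` (smoothed,
#'   clamped at 0), `d1`, `d2`, `window_used`.
#' @export
smooth_trace <- function(trace, cfg = smoother_config(), window = NULL) {
  stopifnot(inherits(trace, "IonTrace"))
  y <- trace$intensity
  w <- if (!is.null(window)) as.integer(window)
       else if (!is.null(cfg$win)) cfg$win else cfg$min_w
  if (w %% 2L == 0L) stop("smoothing window must be odd")
  w <- max(cfg$min_w, min(cfg$max_w, w))
  if (length(y) < cfg$min_w) stop("trace too short to smooth")
  ys <- y
  for (k in seq_len(cfg$times)) {
    ys <- if (cfg$method == "savgol") sg_apply(ys, w, p = 3L, m = 0L)
          else mean_apply(ys, w)
  }
  if (cfg$method == "savgol") {
    # the second-derivative pass uses a wider support (2w-1, capped at
    # max_w): SG double differentiation amplifies noise steeply, and the
    # apex detector needs a noise floor low enough to see genuine minima;
    # the first derivative (baseline-expansion tangents) keeps the
    # smoothing window so tail slopes stay local
    wd <- min(2L * w - 1L, cfg$max_w)
    d1 <- sg_apply(ys, w, p = 3L, m = 1L)
    d2 <- sg_apply(ys, wd, p = 3L, m = 2L)
  } else {
    d1 <- central_diff(ys, 1L)
    d2 <- central_diff(ys, 2L)
  }
  structure(list(rt = trace$rt, y_raw = y, y = pmax(ys, 0),
                 d1 = d1, d2 = d2, window_used = w),
            class = "SmoothedTrace")
}
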