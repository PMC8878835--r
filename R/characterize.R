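# Alternating local extrema (interior indices) of a numeric segment.
segment_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  nz <- which(d != 0)              # plateaus carry the previous direction
  if (length(nz) < 2L) return(integer(0))
  dirs <- sign(d[nz])
  turns <- which(diff(dirs) != 0)
  if (length(turns) == 0L) return(integer(0))
  nz[turns] + 1L
}

#' Estimate trace noise from non-peak scans
#'
#' The noise `N` is the mean absolute peak-to-peak difference between
#' adjacent alternating local extrema of the raw intensities over all scans
#' not covered by a peak region. Segments shorter than 3 scans are skipped.
#' When fewer than two extrema exist in total, a robust fallback is used:
#' 1.4826 x MAD of the first differences of the non-peak raw intensities,
#' flagged via the `fallback` attribute.
#'
#' @param trace The raw `IonTrace`.
#' @param peak_regions Data.frame (or list) with `left_idx` / `right_idx`
#'   columns marking peak-covered scan intervals; may be empty.
#' @return Noise estimate `N` (counts) with attributes `fallback` (logical)
#'   and `n_pairs` (number of extrema pairs used).
#' @export
estimate_noise <- function(trace, peak_regions = NULL) {
  y <- trace$intensity
  n <- length(y)
  mask <- rep(TRUE, n)
  if (!is.null(peak_regions) && length(peak_regions$left_idx) > 0L) {
    for (i in seq_along(peak_regions$left_idx)) {
      lo <- max(1L, peak_regions$left_idx[i])
      hi <- min(n, peak_regions$right_idx[i])
      if (lo <= hi) mask[lo:hi] <- FALSE
    }
  }
  segs <- split(which(mask), cumsum(c(1L, diff(which(mask)) != 1L)))
  diffs <- numeric(0)
  for (seg in segs) {
    if (length(seg) < 3L) next
    ext <- segment_extrema(y[seg])
    if (length(ext) >= 2L)
      diffs <- c(diffs, abs(diff(y[seg][ext])))
  }
  if (length(diffs) >= 1L) {
    N <- mean(diffs)
    attr(N, "fallback") <- FALSE
    attr(N, "n_pairs") <- length(diffs)
    return(N)
  }
  yy <- y[mask]
  N <- if (length(yy) >= 2L) stats::mad(diff(yy)) else 0
  N <- as.numeric(N)
  attr(N, "fallback") <- TRUE
  attr(N, "n_pairs") <- 0L
  N
}

# rt of the crossing of level `lev` by the baseline-corrected smoothed
# trace, walking outward from the apex; capped at the bound.
level_crossing <- function(rt, yc, apex, bound, lev, dir) {
  i <- apex
  repeat {
    j <- i + dir
    if ((dir < 0L && j < bound) || (dir > 0L && j > bound))
      return(list(rt = rt[bound], capped = TRUE))
    if (yc[j] < lev) {
      # linear interpolation between scans j and i
      f <- (yc[i] - lev) / (yc[i] - yc[j])
      return(list(rt = rt[i] + f * (rt[j] - rt[i]), capped = FALSE))
    }
    i <- j
  }
}

#' Compute the quality-metric panel for one bounded peak
#'
#' Given the peak bounds and baseline anchor intensities, computes: the
#' baseline-corrected height `h` at the apex; the trapezoid area of the
#' baseline-corrected raw trace between the bounds (negative values clipped
#' to zero); the signal-to-noise ratio `2h/N`; the base width and the
#' widths at 5%, 10% and 50% (FWHM) of `h`, located on the smoothed
#' baseline-corrected trace by linear interpolation and capped at the
#' bounds; the front (`a`) and tail (`b`) half-widths at 10% height and the
#' tailing factor `b/a` (half-widths at 5% are also reported for
#' reference). All widths are in seconds.
#'
#' @param trace Raw `IonTrace`.
#' @param s `SmoothedTrace`.
#' @param bnd One row of a bounds data.frame (`left_idx`, `right_idx`,
#'   `baseline_left_y`, `baseline_right_y`).
#' @param cand The matching candidate row (`apex_idx`, `left_inf_idx`,
#'   `right_inf_idx`).
#' @param N Noise estimate from [estimate_noise()].
#' @return A one-row data.frame of characteristics.
#' @export
characterize_peak <- function(trace, s, bnd, cand, N) {
  rt <- trace$rt
  L <- bnd$left_idx; R <- bnd$right_idx
  apex <- cand$apex_idx
  stopifnot(L <= apex, apex <= R)
  idx <- L:R
  # straight baseline between the bound anchors, linear in rt
  base <- bnd$baseline_left_y +
    (bnd$baseline_right_y - bnd$baseline_left_y) *
    (rt[idx] - rt[L]) / (rt[R] - rt[L])
  base_at <- function(i) bnd$baseline_left_y +
    (bnd$baseline_right_y - bnd$baseline_left_y) *
    (rt[i] - rt[L]) / (rt[R] - rt[L])
  h <- s$y[apex] - base_at(apex)
  area <- pracma::trapz(rt[idx], pmax(trace$intensity[idx] - base, 0))
  apex_rt <- rt[apex]
  nN <- as.numeric(N)
  out <- data.frame(
    noise = nN, height_cpc = h,
    sn_cpc = if (nN > 0) 2 * h / nN else Inf,
    area_cpc = area,
    w_base = rt[R] - rt[L], fwhm = NA_real_, w05 = NA_real_, w10 = NA_real_,
    front_a = NA_real_, tail_b = NA_real_, tailing_factor = NA_real_,
    front_a5 = NA_real_, tail_b5 = NA_real_,
    n_points = R - L + 1L,
    n_inf_points = cand$right_inf_idx - cand$left_inf_idx + 1L,
    apex_rt = apex_rt,
    width_capped = FALSE, noise_fallback = isTRUE(attr(N, "fallback")),
    valid = h > 0, stringsAsFactors = FALSE)
  if (h <= 0) return(out)
  yc <- numeric(length(rt))
  yc[idx] <- s$y[idx] - base
  capped <- FALSE
  cross <- function(f) {
    lc <- level_crossing(rt, yc, apex, L, f * h, -1L)
    rc <- level_crossing(rt, yc, apex, R, f * h, 1L)
    capped <<- capped || lc$capped || rc$capped
    c(lc$rt, rc$rt)
  }
  c50 <- cross(0.5); c10 <- cross(0.10); c05 <- cross(0.05)
  out$fwhm <- c50[2] - c50[1]
  out$w10 <- c10[2] - c10[1]
  out$w05 <- c05[2] - c05[1]
  out$front_a <- apex_rt - c10[1]
  out$tail_b <- c10[2] - apex_rt
  out$front_a5 <- apex_rt - c05[1]
  out$tail_b5 <- c05[2] - apex_rt
  out$tailing_factor <- if (out$front_a > 0) out$tail_b / out$front_a
                        else NA_real_
  out$width_capped <- capped
  out
}
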