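# Indices of local minima of x (first index of any plateau), restricted to
# strictly negative values.
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n]) + 1L
  idx[x[idx] < 0]
}

#' Detect peak apices along a smoothed trace
#'
#' Peak apices are located as negative local minima of the second derivative
#' cradled by inflection points (zero-crossings of `d2`). A minimum
#' qualifies only if its magnitude exceeds a robust noise gate,
#' `|d2| > g * MAD(d2) / 0.6745` (`g = d2_gate`, 0 disables). Inflection
#' indices are the inner (peak-side) scans of the cradling zero-crossings.
#' When two qualifying minima share a negative second-derivative stretch
#' with no zero-crossing between them (a rounded pair), the intervening
#' local maximum of `d2` anchors both facing sides instead. The apex is
#' refined to the maximum of the smoothed intensity between the inflection
#' points when that maximum is strictly interior; otherwise (monotone
#' flank, e.g. a shoulder member) the second-derivative minimum itself is
#' kept.
#'
#' @param s A `SmoothedTrace` from [smooth_trace()].
#' @param d2_gate Robust gate multiplier `g` (default 2).
#' @return A data.frame with one row per candidate, ordered by `apex_idx`:
#'   `apex_idx`, `left_inf_idx`, `right_inf_idx`, `d2_min`,
#'   `left_inf_type`/`right_inf_type` (`"crossing"` or `"d2max"`).
#' @export
detect_apices <- function(s, d2_gate = 2) {
  stopifnot(inherits(s, "SmoothedTrace"))
  d2 <- s$d2
  n <- length(d2)
  mins <- local_minima(d2)
  # the shrunken-window derivative estimates in the outermost scans are
  # unreliable; never seed a candidate there
  mins <- mins[mins > 3L & mins < n - 2L]
  if (length(mins) > 0L && d2_gate > 0) {
    scale <- stats::mad(d2)             # 1.4826 * median|d2 - med| = MAD/0.6745
    mins <- mins[abs(d2[mins]) > d2_gate * scale]
  }
  # floating-point jitter on flat stretches must never seed a candidate:
  # genuine curvature is bounded away from zero relative to the intensity
  # scale of the trace
  if (length(mins) > 0L)
    mins <- mins[abs(d2[mins]) > 1e-10 * max(abs(s$y), 1)]
  empty <- data.frame(apex_idx = integer(0), left_inf_idx = integer(0),
                      right_inf_idx = integer(0), d2_min = numeric(0),
                      d2_min_idx = integer(0),
                      left_inf_type = character(0),
                      right_inf_type = character(0),
                      stringsAsFactors = FALSE)
  if (length(mins) == 0L) return(empty)

  # walk outward from a d2 minimum to the cradling zero-crossing (inner
  # index) or, failing that before `limit`, the d2 local maximum in between
  find_edge <- function(i, dir, limit) {
    j <- i
    repeat {
      k <- j + dir
      if ((dir < 0L && k < limit) || (dir > 0L && k > limit)) break
      if (d2[k] >= 0) {
        # inner (peak-side) index of the crossing; an exact zero IS the crossing
        return(list(idx = if (d2[k] == 0) k else j, type = "crossing"))
      }
      j <- k
    }
    NULL
  }
  out <- vector("list", length(mins))
  for (ii in seq_along(mins)) {
    i <- mins[ii]
    llim <- if (ii > 1L) mins[ii - 1L] else 1L
    rlim <- if (ii < length(mins)) mins[ii + 1L] else n
    left <- find_edge(i, -1L, llim)
    if (is.null(left) && ii > 1L) {
      # rounded pair: anchor at the d2 local maximum between the two minima
      seg <- (mins[ii - 1L] + 1L):(i - 1L)
      if (length(seg) > 0L)
        left <- list(idx = seg[which.max(d2[seg])], type = "d2max")
    }
    right <- find_edge(i, 1L, rlim)
    if (is.null(right) && ii < length(mins)) {
      seg <- (i + 1L):(mins[ii + 1L] - 1L)
      if (length(seg) > 0L)
        right <- list(idx = seg[which.max(d2[seg])], type = "d2max")
    }
    if (is.null(left) || is.null(right)) next   # uncradled at trace edge
    if (left$idx >= i || right$idx <= i) next
    # refine apex to the smoothed-intensity crest between the inflections
    seg <- left$idx:right$idx
    am <- seg[which.max(s$y[seg])]
    apex <- if (am > left$idx && am < right$idx) am else i
    out[[ii]] <- data.frame(apex_idx = apex, left_inf_idx = left$idx,
                            right_inf_idx = right$idx, d2_min = d2[i],
                            d2_min_idx = i,
                            left_inf_type = left$type,
                            right_inf_type = right$type,
                            stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$apex_idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match a picked peak to a detected apex
#'
#' Returns the index (into `candidates`) of the detected apex whose
#' retention time lies within the picked peak's `[rtmin, rtmax]` and is
#' nearest to the reported `rt`; `NA` when no candidate apex falls inside
#' the picked bounds (downstream this triggers the no-peak-signature
#' filter).
#'
#' @param candidates Candidate data.frame from [detect_apices()].
#' @param peak_row One row of a peak table (`rt`, `rtmin`, `rtmax`).
#' @param rt Retention-time vector of the trace the candidates refer to.
#' @return Integer candidate index, or `NA_integer_`.
#' @export
match_xcms_peak <- function(candidates, peak_row, rt) {
  if (nrow(candidates) == 0L) return(NA_integer_)
  apex_rt <- rt[candidates$apex_idx]
  inside <- which(apex_rt >= peak_row$rtmin & apex_rt <= peak_row$rtmax)
  if (length(inside) == 0L) return(NA_integer_)
  inside[which.min(abs(apex_rt[inside] - peak_row$rt))]
}
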