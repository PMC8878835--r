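#' Expand peak boundaries from the inflection points to the baseline
#'
#' Implements iterative baseline expansion: an initial baseline is drawn
#' between the front and tail inflection points; at each step the slope
#' difference between the tangent (smoothed first derivative) at each bound
#' and the current baseline is compared against a threshold expressed as a
#' percentage (`liftoff` for the front, `touchdown` for the tail) of the
#' corresponding slope difference at the initial baseline. While a side's
#' difference exceeds its threshold, that bound moves one scan outward;
#' sides are advanced alternately with the side of larger normalized excess
#' stepped first. A side terminates when its criterion holds, when the trace
#' edge is reached (`boundary_type = "edge"`), or when it reaches a stop
#' index (an adjacent candidate's inflection region, after which cluster
#' handling takes over). A side whose initial slope difference is not
#' positive terminates immediately (percent thresholds are meaningless
#' there). All slopes are in counts per scan.
#'
#' @param s A `SmoothedTrace`.
#' @param cand One row of the candidate data.frame from [detect_apices()].
#' @param cfg An [expansion_config()].
#' @param left_stop,right_stop Scan indices beyond which a bound may not
#'   move (defaults: trace edges).
#' @return A one-row data.frame: `left_idx`, `right_idx`, `baseline_left_y`,
#'   `baseline_right_y`, `btype_left`, `btype_right` (`"expanded"` or
#'   `"edge"`).
#' @export
expand_baseline <- function(s, cand, cfg = expansion_config(),
                            left_stop = 1L, right_stop = length(s$y)) {
  stopifnot(inherits(s, "SmoothedTrace"))
  y <- s$y; d1 <- s$d1
  n <- length(y)
  L <- cand$left_inf_idx
  R <- cand$right_inf_idx
  left_stop <- max(1L, left_stop)
  right_stop <- min(n, right_stop)
  btl <- "expanded"; btr <- "expanded"

  if (R - L <= 1L) {                     # degenerate candidate
    return(data.frame(left_idx = L, right_idx = R,
                      baseline_left_y = y[L], baseline_right_y = y[R],
                      btype_left = "expanded", btype_right = "expanded",
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }

  m0 <- (y[R] - y[L]) / (R - L)
  df0 <- d1[L] - m0                       # front slope difference
  dt0 <- m0 - d1[R]                       # tail slope difference
  Tf <- cfg$liftoff / 100 * df0
  Tt <- cfg$touchdown / 100 * dt0
  front_active <- df0 > 0
  tail_active <- dt0 > 0

  while (front_active || tail_active) {
    m <- (y[R] - y[L]) / (R - L)
    df <- d1[L] - m
    dt <- m - d1[R]
    if (front_active && df <= Tf) front_active <- FALSE
    if (tail_active && dt <= Tt) tail_active <- FALSE
    if (!front_active && !tail_active) break
    # pick the side with the larger normalized excess
    step_front <- if (front_active && tail_active)
      (df / df0) >= (dt / dt0) else front_active
    if (step_front) {
      if (L <= left_stop) {
        front_active <- FALSE
        if (L <= 1L) btl <- "edge"
      } else L <- L - 1L
    } else {
      if (R >= right_stop) {
        tail_active <- FALSE
        if (R >= n) btr <- "edge"
      } else R <- R + 1L
    }
  }
  data.frame(left_idx = L, right_idx = R,
             baseline_left_y = y[L], baseline_right_y = y[R],
             btype_left = btl, btype_right = btr,
             degenerate = FALSE, stringsAsFactors = FALSE)
}
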