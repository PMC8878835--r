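#' Group peaks with overlapping bounds into co-eluting clusters
#'
#' Clusters are the transitive closure of pairwise interval overlap of the
#' expanded baseline bounds (intervals sharing a scan count as overlapping).
#' Cluster bounds are the union extremes and the cluster baseline is drawn
#' between them on the smoothed trace.
#'
#' @param bounds Data.frame of expanded bounds (one row per candidate,
#'   sorted by apex) from [expand_baseline()].
#' @param s The `SmoothedTrace` the bounds refer to.
#' @return A list of clusters; each is a list with `members` (candidate row
#'   indices), `left_idx`, `right_idx`, `baseline_left_y`,
#'   `baseline_right_y`.
#' @export
group_clusters <- function(bounds, s) {
  n <- nrow(bounds)
  if (n == 0L) return(list())
  clusters <- list()
  cur <- list(members = 1L, left_idx = bounds$left_idx[1L],
              right_idx = bounds$right_idx[1L])
  if (n > 1L) for (i in 2:n) {
    if (bounds$left_idx[i] <= cur$right_idx) {
      cur$members <- c(cur$members, i)
      cur$left_idx <- min(cur$left_idx, bounds$left_idx[i])
      cur$right_idx <- max(cur$right_idx, bounds$right_idx[i])
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- list(members = i, left_idx = bounds$left_idx[i],
                  right_idx = bounds$right_idx[i])
    }
  }
  clusters[[length(clusters) + 1L]] <- cur
  lapply(clusters, function(cl) {
    cl$baseline_left_y <- s$y[cl$left_idx]
    cl$baseline_right_y <- s$y[cl$right_idx]
    cl
  })
}

# Classify and locate the separator between two adjacent candidates.
# The curvature decides the pair class first: if the second derivative
# stays negative between the two d2 minima (no zero-crossing pair), the
# pair is rounded and separated at the intervening d2 maximum. With a
# zero-crossing pair present, a local minimum of the smoothed intensity
# strictly between the apices makes a valley boundary at the lowest such
# point; otherwise the pair is a shoulder, separated at the d2 maximum.
locate_separator <- function(s, c1, c2) {
  y <- s$y; d2 <- s$d2
  a1 <- c1$apex_idx; a2 <- c2$apex_idx
  m1 <- c1$d2_min_idx; m2 <- c2$d2_min_idx
  if (a2 - a1 < 2L) return(list(type = "rounded", idx = a1 + 1L))
  dseg <- (m1 + 1L):(m2 - 1L)
  k <- dseg[which.max(d2[dseg])]
  if (d2[k] < 0) return(list(type = "rounded", idx = k))
  seg <- (a1 + 1L):(a2 - 1L)
  is_min <- vapply(seg, function(j)
    y[j] <= y[j - 1L] && y[j] <= y[j + 1L], logical(1))
  if (any(is_min)) {
    cand <- seg[is_min]
    return(list(type = "valley", idx = cand[which.min(y[cand])]))
  }
  list(type = "shoulder", idx = k)
}

#' Resolve separators within a co-eluting peak cluster
#'
#' For each adjacent apex pair the inter-peak boundary is set at the lowest
#' smoothed intensity between the apices when a valley exists; otherwise at
#' the second-derivative maximum between the two second-derivative minima
#' (a shoulder when that maximum crosses zero, a rounded boundary when the
#' second derivative stays negative). Shoulder/rounded pairs whose smaller
#' (lower-apex) member has fewer than `min_shoulder_pts` /
#' `min_rounded_pts` scans between its apex and the bounding
#' second-derivative maximum are merged into the taller member. Merging is
#' repeated until stable, so the result is idempotent.
#'
#' @param cluster A cluster from [group_clusters()].
#' @param s The `SmoothedTrace`.
#' @param candidates Candidate data.frame from [detect_apices()].
#' @param min_shoulder_pts,min_rounded_pts Merge thresholds in scans.
#' @return The cluster with `members` possibly reduced, `separators` (a
#'   data.frame with `type`, `idx`, one row per surviving adjacent pair) and
#'   `merged_into` (named integer vector mapping each dropped candidate row
#'   to the surviving row it merged into, possibly empty).
#' @export
resolve_separators <- function(cluster, s, candidates,
                               min_shoulder_pts = 3L, min_rounded_pts = 3L) {
  members <- cluster$members
  cluster$orig_members <- members
  merged_into <- integer(0)
  repeat {
    if (length(members) < 2L) break
    seps <- lapply(seq_len(length(members) - 1L), function(i)
      locate_separator(s, candidates[members[i], ],
                       candidates[members[i + 1L], ]))
    merged <- FALSE
    for (i in seq_along(seps)) {
      sp <- seps[[i]]
      if (sp$type == "valley") next
      m1 <- members[i]; m2 <- members[i + 1L]
      smaller <- if (s$y[candidates$apex_idx[m1]] >=
                     s$y[candidates$apex_idx[m2]]) m2 else m1
      taller <- if (smaller == m1) m2 else m1
      gap <- abs(candidates$apex_idx[smaller] - sp$idx)
      thr <- if (sp$type == "shoulder") min_shoulder_pts else min_rounded_pts
      if (gap < thr) {
        merged_into[as.character(smaller)] <- taller
        members <- setdiff(members, smaller)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  cluster$members <- members
  cluster$merged_into <-
    if (length(merged_into)) {
      v <- as.integer(merged_into); names(v) <- names(merged_into); v
    } else integer(0)
  cluster$separators <- if (length(members) >= 2L) {
    do.call(rbind, lapply(seq_len(length(members) - 1L), function(i) {
      sp <- locate_separator(s, candidates[members[i], ],
                             candidates[members[i + 1L], ])
      data.frame(type = sp$type, idx = sp$idx, stringsAsFactors = FALSE)
    }))
  } else data.frame(type = character(0), idx = integer(0),
                    stringsAsFactors = FALSE)
  cluster
}

#' Per-member bounds and baselines within a cluster
#'
#' Member bounds are the cluster extremes at the outer edges and the
#' separator indices at shared edges; baseline values are the linear
#' cluster baseline (between the cluster extremes on the smoothed trace)
#' evaluated at those bounds.
#'
#' @param cluster A resolved cluster from [resolve_separators()].
#' @param s The `SmoothedTrace`.
#' @param bounds The per-candidate expanded bounds data.frame.
#' @return Data.frame with one row per member: `member`, `left_idx`,
#'   `right_idx`, `baseline_left_y`, `baseline_right_y`, `btype_left`,
#'   `btype_right`.
#' @export
member_bounds <- function(cluster, s, bounds) {
  members <- cluster$members
  k <- length(members)
  base_at <- function(idx) {
    if (cluster$right_idx == cluster$left_idx) return(cluster$baseline_left_y)
    w <- (idx - cluster$left_idx) / (cluster$right_idx - cluster$left_idx)
    (1 - w) * cluster$baseline_left_y + w * cluster$baseline_right_y
  }
  orig <- if (!is.null(cluster$orig_members)) cluster$orig_members
          else members
  if (k == 1L) {
    # a singleton spans the whole cluster (absorbing any merged members)
    return(data.frame(member = members,
                      left_idx = cluster$left_idx,
                      right_idx = cluster$right_idx,
                      baseline_left_y = cluster$baseline_left_y,
                      baseline_right_y = cluster$baseline_right_y,
                      btype_left = bounds$btype_left[orig[1L]],
                      btype_right = bounds$btype_right[orig[length(orig)]],
                      stringsAsFactors = FALSE))
  }
  sep_idx <- cluster$separators$idx
  sep_type <- cluster$separators$type
  lefts <- c(cluster$left_idx, sep_idx)
  rights <- c(sep_idx, cluster$right_idx)
  data.frame(member = members, left_idx = lefts, right_idx = rights,
             baseline_left_y = vapply(lefts, base_at, numeric(1)),
             baseline_right_y = vapply(rights, base_at, numeric(1)),
             btype_left = c(bounds$btype_left[orig[1L]], sep_type),
             btype_right = c(sep_type, bounds$btype_right[orig[length(orig)]]),
             stringsAsFactors = FALSE)
}

#' Fit an exponentially modified Gaussian mixture to a cluster
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of a sum of EMG
#' components, one per cluster member, over the cluster region of the raw
#' trace, initialized from the apex positions and inflection widths. This
#' refines peak characteristics for strongly overlapped clusters; it is
#' informational and never alters filter decisions.
#'
#' @param cluster A resolved cluster.
#' @param trace The raw `IonTrace`.
#' @param s The `SmoothedTrace`.
#' @param candidates Candidate data.frame.
#' @return A list with `converged` (logical), `params` (data.frame
#'   `amplitude`, `mu`, `sigma`, `tau` per member, `NULL` on failure),
#'   `rms` residual.
#' @export
deconvolve_emg <- function(cluster, trace, s, candidates) {
  members <- cluster$members
  idx <- cluster$left_idx:cluster$right_idx
  t <- trace$rt[idx]
  yv <- trace$intensity[idx]
  base <- seq(cluster$baseline_left_y, cluster$baseline_right_y,
              length.out = length(idx))
  yv <- yv - base
  dt <- stats::median(diff(trace$rt))
  k <- length(members)
  p0 <- numeric(0)
  for (m in members) {
    ai <- candidates$apex_idx[m]
    sig0 <- max(dt, (candidates$right_inf_idx[m] -
                       candidates$left_inf_idx[m]) / 2 * dt)
    p0 <- c(p0, max(s$y[ai], 1), trace$rt[ai], sig0, sig0 / 2)
  }
  model <- function(p) {
    out <- numeric(length(t))
    for (j in seq_len(k)) {
      q <- p[(4 * j - 4) + 1:4]
      out <- out + emg_profile(t, mu = q[2], sigma = abs(q[3]),
                               tau = abs(q[4]), amplitude = abs(q[1]))
    }
    out
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) model(p) - yv,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$info %in% c(1, 2, 3, 4)
  if (ok) {
    res <- model(fit$par) - yv
    tot <- sum((yv - mean(yv))^2)
    ok <- tot > 0 && sum(res^2) / tot < 0.5   # fit must explain the signal
  }
  if (!ok)
    return(list(converged = FALSE, params = NULL, rms = NA_real_))
  p <- fit$par
  params <- data.frame(
    member = members,
    amplitude = abs(p[seq(1, 4 * k, by = 4)]),
    mu = p[seq(2, 4 * k, by = 4)],
    sigma = abs(p[seq(3, 4 * k, by = 4)]),
    tau = abs(p[seq(4, 4 * k, by = 4)]))
  params$area <- params$amplitude * params$sigma * sqrt(2 * pi)
  list(converged = TRUE, params = params,
       rms = sqrt(mean((model(p) - yv)^2)))
}
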