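.empty_chars <- function() {
  data.frame(noise = NA_real_, height_cpc = NA_real_, sn_cpc = NA_real_,
             area_cpc = NA_real_, w_base = NA_real_, fwhm = NA_real_,
             w05 = NA_real_, w10 = NA_real_, front_a = NA_real_,
             tail_b = NA_real_, tailing_factor = NA_real_,
             front_a5 = NA_real_, tail_b5 = NA_real_,
             n_points = NA_integer_, n_inf_points = NA_integer_,
             apex_rt = NA_real_, width_capped = FALSE,
             noise_fallback = FALSE, valid = FALSE, stringsAsFactors = FALSE)
}

# Full per-peak evaluation: extract, smooth, detect, expand, cluster,
# characterize. Returns chars (1 row), decision fields and optional detail.
process_peak <- function(run, row, cfg, keep_detail = FALSE) {
  w <- row$rtmax - row$rtmin
  lo <- max(run$rt_range[1], row$rtmin - cfg$eic_k * w)
  hi <- min(run$rt_range[2], row$rtmax + cfg$eic_k * w)
  trace <- extract_eic(run, row$mz, cfg$filters$ppm, lo, hi,
                       origin_peak_id = row$peak_id)
  scan_dt <- stats::median(diff(trace$rt))
  sigma_scans <- max(w / 4 / scan_dt, 0.5)
  win <- auto_window(sigma_scans, cfg$smoother)
  s <- smooth_trace(trace, cfg$smoother, window = win)
  cands <- detect_apices(s, cfg$d2_gate)
  na <- nrow(cands)
  res <- list(chars = .empty_chars(), matched = NA_integer_,
              boundary_type_left = NA_character_,
              boundary_type_right = NA_character_, merged = FALSE,
              detail = NULL)
  if (na == 0L) {
    if (keep_detail) res$detail <- list(trace = trace, smoothed = s,
                                        candidates = cands)
    return(res)
  }
  bounds <- do.call(rbind, lapply(seq_len(na), function(i)
    expand_baseline(s, cands[i, ], cfg$expansion,
                    left_stop = if (i > 1L) cands$right_inf_idx[i - 1L] else 1L,
                    right_stop = if (i < na) cands$left_inf_idx[i + 1L]
                                 else length(s$y))))
  clusters <- group_clusters(bounds, s)
  clusters <- lapply(clusters, resolve_separators, s = s,
                     candidates = cands,
                     min_shoulder_pts = cfg$filters$min_shoulder_pts,
                     min_rounded_pts = cfg$filters$min_rounded_pts)
  mb <- do.call(rbind, lapply(clusters, member_bounds, s = s,
                              bounds = bounds))
  merged_map <- unlist(lapply(clusters, function(cl)
    cl$merged_into), use.names = TRUE)
  # noise from scans outside every cluster region of the raw trace
  regions <- data.frame(
    left_idx = vapply(clusters, `[[`, integer(1), "left_idx"),
    right_idx = vapply(clusters, `[[`, integer(1), "right_idx"))
  N <- estimate_noise(trace, regions)
  # match the picked peak among the originally detected apices
  mi <- match_xcms_peak(cands, row, trace$rt)
  if (!is.na(mi)) {
    # follow merges to the surviving member
    target <- mi
    hops <- 0L
    while (!is.null(merged_map) &&
           as.character(target) %in% names(merged_map) && hops < na) {
      target <- merged_map[[as.character(target)]]
      hops <- hops + 1L
    }
    res$merged <- !identical(target, mi)
    brow <- mb[mb$member == target, , drop = FALSE]
    if (nrow(brow) == 1L) {
      ch <- characterize_peak(trace, s, brow, cands[target, ], N)
      res$chars <- ch
      res$matched <- target
      res$boundary_type_left <- brow$btype_left
      res$boundary_type_right <- brow$btype_right
    }
  } else {
    res$chars$noise <- as.numeric(N)
  }
  if (cfg$deconvolve && !is.na(res$matched)) {
    for (cl in clusters) {
      if (res$matched %in% cl$members) {
        dec <- deconvolve_emg(cl, trace, s, cands)
        res$emg <- dec
        break
      }
    }
  }
  if (keep_detail)
    res$detail <- list(trace = trace, smoothed = s, candidates = cands,
                       bounds = bounds, clusters = clusters,
                       member_bounds = mb, noise = N)
  res
}

#' Characterize and filter a picked-peak table against raw data
#'
#' The core pipeline: for every row of the peak table, the ion trace is
#' extracted over an extended window (`[rtmin - k*w, rtmax + k*w]`,
#' `w = rtmax - rtmin`), smoothed, scanned for apices on the second
#' derivative, bounded by baseline expansion, cluster-resolved, and
#' characterized; the quality filters then yield a keep/remove decision per
#' row. Per-peak processing failures are caught, logged and flagged, never
#' fatal.
#'
#' @param run A `RawRun` from [read_mzml()].
#' @param peak_table A validated peak table (see [read_peak_table()]).
#' @param cfg A [run_config()].
#' @param keep_details Keep per-peak traces and intermediate objects
#'   (memory-heavy; default `FALSE`).
#' @return A list: `chars` (one characteristics row per input row, plus
#'   `boundary_type_left/right`, `merged`, `status`), `decisions`
#'   (`keep`, `filter_reasons`), `table` (the combined data.frame) and,
#'   when requested, `details`.
#' @export
characterize_peaks <- function(run, peak_table, cfg = run_config(),
                               keep_details = FALSE) {
  peak_table <- validate_peak_table(peak_table)
  n <- nrow(peak_table)
  chars_l <- vector("list", n)
  dec_l <- vector("list", n)
  details <- if (keep_details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    row <- peak_table[i, ]
    res <- tryCatch(process_peak(run, row, cfg, keep_detail = keep_details),
                    error = function(e)
                      list(chars = .empty_chars(), matched = NA_integer_,
                           boundary_type_left = NA_character_,
                           boundary_type_right = NA_character_,
                           merged = FALSE, detail = NULL,
                           status = conditionMessage(e)))
    ch <- res$chars
    ch$boundary_type_left <- res$boundary_type_left
    ch$boundary_type_right <- res$boundary_type_right
    ch$merged <- res$merged
    ch$status <- if (is.null(res$status)) "ok" else res$status
    chars_l[[i]] <- ch
    dec_l[[i]] <- apply_filters(if (isTRUE(res$chars$valid)) res$chars
                                else NULL, cfg$filters)
    if (keep_details) details[[i]] <- res$detail
  }
  chars <- do.call(rbind, chars_l)
  decisions <- do.call(rbind, dec_l)
  rownames(chars) <- rownames(decisions) <- NULL
  out <- list(chars = chars, decisions = decisions,
              table = cbind(peak_table, chars, decisions))
  if (keep_details) out$details <- details
  out
}

filters_as_list <- function(cfg) {
  f <- cfg$filters; s <- cfg$smoother; e <- cfg$expansion
  list(ppm = f$ppm, min_pts = f$min_pts, min_inf_width = f$min_inf_width,
       min_sn = f$min_sn, min_intensity = f$min_intensity,
       min_shoulder_pts = f$min_shoulder_pts,
       min_rounded_pts = f$min_rounded_pts,
       interval_tf = f$interval_tf, min_fwhm = f$min_fwhm,
       min_w = s$min_w, max_w = s$max_w, smooth_method = s$method,
       smooth_times = s$times, smooth_win = s$win, max_sigma = s$max_sigma,
       liftoff = e$liftoff, touchdown = e$touchdown,
       eic_k = cfg$eic_k, d2_gate = cfg$d2_gate)
}

#' Run the characterization pipeline on files
#'
#' Reads an mzML file and a peak-table CSV, runs [characterize_peaks()] per
#' sample, and writes `characterized.csv`, `kept.csv`, `removed.csv`,
#' `summary.json` and `peakchar.log` into `out_dir`. When the peak table
#' holds several samples, `mzml` may be a named character vector mapping
#' sample names to files; a single unnamed path is used for all samples.
#'
#' @param mzml Path(s) to centroided mzML file(s).
#' @param peaks Path to the peak-table CSV (or a data.frame).
#' @param config Path to a YAML configuration, a [run_config()], or `NULL`
#'   for defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the combined table, the partition and the
#'   summary.
#' @export
cmd_characterize <- function(mzml, peaks, config = NULL, out_dir = ".") {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  tab <- if (is.data.frame(peaks)) validate_peak_table(peaks)
         else read_peak_table(peaks)
  for (p in unname(mzml))
    if (!file.exists(p)) stop("mzML file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  samples <- unique(tab$sample)
  parts <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sm <- samples[si]
    path <- if (!is.null(names(mzml)) && sm %in% names(mzml)) mzml[[sm]]
            else unname(mzml)[1]
    logf("sample %s: reading %s", sm, path)
    run <- read_mzml(path)
    sub <- tab[tab$sample == sm, , drop = FALSE]
    logf("sample %s: characterizing %d peaks", sm, nrow(sub))
    parts[[si]] <- characterize_peaks(run, sub, cfg)$table
  }
  full <- do.call(rbind, parts)
  full <- full[match(tab$peak_id, full$peak_id), , drop = FALSE]
  rownames(full) <- NULL
  part <- filter_table(full, full[, c("keep", "filter_reasons")])
  utils::write.csv(full, file.path(out_dir, "characterized.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(part$kept, file.path(out_dir, "kept.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(part$removed, file.path(out_dir, "removed.csv"),
                   row.names = FALSE, na = "")
  summary <- list(schema_version = 1L, n = part$summary$n,
                  n_kept = part$summary$n_kept,
                  n_removed = part$summary$n_removed,
                  removed_fraction = part$summary$removed_fraction,
                  reason_counts = part$summary$reason_counts,
                  config = filters_as_list(cfg))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("done: %d kept, %d removed", part$summary$n_kept,
       part$summary$n_removed)
  writeLines(log_lines, file.path(out_dir, "peakchar.log"))
  invisible(list(table = full, kept = part$kept, removed = part$removed,
                 summary = summary))
}

#' Generate and write a synthetic benchmark
#'
#' Writes a centroided mzML run, a chromPeaks-convention `peaks.csv`, a
#' `labels.csv` with the true/false ground truth and a `truth.csv` with the
#' analytic characteristics of the true peaks.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_true,n_false Entry counts (default 100 each).
#' @param spec Optional YAML file overriding generator settings
#'   (`rt_max`, `scan_dt`, `white_sd`, `baseline_level`,
#'   `ripple_amplitude`, `ripple_period`, `sn_strata`).
#' @return Invisibly, the benchmark list from [gen_benchmark()].
#' @export
cmd_synth <- function(out_dir = ".", seed = 42L, n_true = 100L,
                      n_false = 100L, spec = NULL) {
  opts <- if (!is.null(spec)) yaml::read_yaml(spec) else list()
  args <- c(list(n_true = n_true, n_false = n_false, seed = seed),
            opts[intersect(names(opts),
                           c("rt_max", "scan_dt", "white_sd",
                             "baseline_level", "ripple_amplitude",
                             "ripple_period", "sn_strata"))])
  bench <- do.call(gen_benchmark, args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mzml(bench$run, file.path(out_dir, "synthetic.mzML"))
  utils::write.csv(bench$peaks, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(bench$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(bench$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, na = "")
  invisible(bench)
}

#' Diagnostic plots of characterized peaks
#'
#' For each requested peak id, draws the raw ion trace (dashed grey), the
#' smoothed trace (solid black), the expanded baseline (dashed red) and the
#' detected bounds (red points) into a PNG file named after the id. Unknown
#' ids are skipped with a warning.
#'
#' @param characterized Path to `characterized.csv` (or the data.frame).
#' @param mzml Path to the mzML file the peaks were characterized against.
#' @param ids Character vector of `peak_id`s to plot (may be empty).
#' @param out_dir Output directory for PNG files.
#' @param config Configuration as in [cmd_characterize()].
#' @return Invisibly, the paths of the files written.
#' @export
cmd_plot <- function(characterized, mzml, ids, out_dir = ".",
                     config = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  tab <- if (is.data.frame(characterized)) characterized
         else utils::read.csv(characterized, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- read_mzml(mzml)
  written <- character(0)
  for (id in ids) {
    ri <- which(tab$peak_id == id)
    if (length(ri) != 1L) {
      warning("unknown peak id, skipped: ", id)
      next
    }
    row <- tab[ri, ]
    res <- tryCatch(process_peak(run, row, cfg, keep_detail = TRUE),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning("could not process peak, skipped: ", id)
      next
    }
    d <- res$detail
    path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", id),
                                      ".png"))
    grDevices::png(path, width = 800, height = 500)
    graphics::plot(d$trace$rt, d$trace$intensity, type = "l", lty = 2,
                   col = "grey50", xlab = "retention time (s)",
                   ylab = "intensity (counts)", main = id)
    graphics::lines(d$smoothed$rt, d$smoothed$y, col = "black")
    if (!is.na(res$matched)) {
      bm <- d$member_bounds[d$member_bounds$member == res$matched, ]
      graphics::segments(d$trace$rt[bm$left_idx], bm$baseline_left_y,
                         d$trace$rt[bm$right_idx], bm$baseline_right_y,
                         col = "red", lty = 2)
      graphics::points(d$trace$rt[c(bm$left_idx, bm$right_idx)],
                       c(bm$baseline_left_y, bm$baseline_right_y),
                       col = "red", pch = 19)
    }
    grDevices::dev.off()
    written <- c(written, path)
  }
  invisible(written)
}
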