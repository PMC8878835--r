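#' Construct a raw run in memory
#'
#' @param rt Strictly increasing scan retention times (seconds).
#' @param spectra List of `cbind(mz, intensity)` matrices, one per scan.
#' @param run_id Run identifier.
#' @return A `RawRun`.
#' @export
raw_run <- function(rt, spectra, run_id = "run") {
  stopifnot(all(diff(rt) > 0), length(rt) == length(spectra))
  new_raw_run(rt, lapply(spectra, function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("mz", "intensity")
    m
  }), run_id)
}

#' Construct an ion trace from vectors
#'
#' @param rt Strictly increasing retention times (seconds).
#' @param intensity Non-negative intensities (counts), same length as `rt`.
#' @param mz_target,ppm Extraction window metadata (optional).
#' @param origin_peak_id Optional picked-peak id.
#' @return An `IonTrace`.
#' @export
ion_trace <- function(rt, intensity, mz_target = NA_real_, ppm = NA_real_,
                      origin_peak_id = NA_character_) {
  stopifnot(length(rt) == length(intensity), all(diff(rt) > 0),
            all(intensity >= 0))
  new_ion_trace(rt, intensity, mz_target, ppm, origin_peak_id)
}

new_raw_run <- function(rt, spectra, run_id = "run") {
  structure(list(rt = as.numeric(rt), spectra = spectra,
                 run_id = run_id,
                 rt_range = range(as.numeric(rt))),
            class = "RawRun")
}

#' @export
print.RawRun <- function(x, ...) {
  cat(sprintf("RawRun '%s': %d MS1 scans, rt %.1f-%.1f s\n",
              x$run_id, length(x$rt), x$rt_range[1], x$rt_range[2]))
  invisible(x)
}

#' Read a centroided mzML file
#'
#' Reads all MS1 spectra from an mzML file into an in-memory run. Scans are
#' sorted by retention time. The data are assumed to be centroided;
#' profile-mode spectra are accepted with a warning (sums over the m/z window
#' then approximate profile-integrated intensity).
#'
#' @param path Path to an mzML file.
#' @return A `RawRun`: retention times (seconds), a list of `cbind(mz,
#'   intensity)` matrices (one per scan), and the run id (file base name).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("unreadable mzML file: ", path,
                                          " (", conditionMessage(e), ")"))
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 spectra in file: ", path)
  if (any(!is.na(hd$centroided[ms1]) & !hd$centroided[ms1]))
    warning("file contains profile-mode MS1 spectra; treating as centroided: ",
            path)
  pk <- mzR::peaks(fh, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- hd$retentionTime[ms1]
  ord <- order(rt)
  spectra <- lapply(pk[ord], function(m) {
    m <- as.matrix(m)
    colnames(m) <- c("mz", "intensity")
    m
  })
  new_raw_run(rt[ord], spectra, run_id = basename(path))
}

new_ion_trace <- function(rt, intensity, mz_target, ppm,
                          origin_peak_id = NA_character_,
                          scan_index_offset = 0L) {
  structure(list(rt = as.numeric(rt), intensity = as.numeric(intensity),
                 mz_target = mz_target, ppm = ppm,
                 origin_peak_id = origin_peak_id,
                 scan_index_offset = as.integer(scan_index_offset)),
            class = "IonTrace")
}

#' Extract an ion chromatogram from a raw run
#'
#' Builds the extracted ion chromatogram (EIC) for `mz_target` over a
#' retention-time window. Each scan with rt in `[rt_lo, rt_hi]` contributes
#' one trace point whose intensity is the sum of all centroid intensities
#' with `|mz - mz_target| / mz_target <= ppm * 1e-6`; scans with no matching
#' centroid contribute an explicit zero, so the trace is defined on the full
#' scan grid of the window.
#'
#' @param run A `RawRun` from [read_mzml()].
#' @param mz_target Target m/z.
#' @param ppm m/z tolerance in parts per million (> 0).
#' @param rt_lo,rt_hi Retention-time window in seconds (`rt_lo < rt_hi`).
#' @param origin_peak_id Optional id of the picked peak this trace belongs to.
#' @return An `IonTrace`.
#' @export
extract_eic <- function(run, mz_target, ppm, rt_lo, rt_hi,
                        origin_peak_id = NA_character_) {
  stopifnot(inherits(run, "RawRun"), ppm > 0)
  if (rt_lo >= rt_hi) stop("rt_lo must be < rt_hi")
  sel <- which(run$rt >= rt_lo & run$rt <= rt_hi)
  if (length(sel) == 0L) stop("empty RT window [", rt_lo, ", ", rt_hi, "]")
  tol <- mz_target * ppm * 1e-6
  ints <- vapply(run$spectra[sel], function(m) {
    hit <- abs(m[, 1L] - mz_target) <= tol
    if (any(hit)) sum(m[hit, 2L]) else 0
  }, numeric(1))
  new_ion_trace(run$rt[sel], ints, mz_target, ppm,
                origin_peak_id = origin_peak_id,
                scan_index_offset = sel[1L] - 1L)
}

.peak_table_required <- c("mz", "rt", "rtmin", "rtmax")
.peak_table_optional <- c(mzmin = NA_real_, mzmax = NA_real_, into = NA_real_,
                          maxo = NA_real_, sn = NA_real_)

#' Read a picked-peak table
#'
#' Reads a CSV peak table in the XCMS `chromPeaks` column convention
#' (`mz, mzmin, mzmax, rt, rtmin, rtmax, into, maxo, sn, sample`; retention
#' times in seconds, one row per picked peak in one sample). Only `mz, rt,
#' rtmin, rtmax` are required; missing optional columns are filled with `NA`
#' (`sample` with `"sample1"`). Rows violating `rtmin < rt < rtmax` or
#' `mzmin <= mz <= mzmax` are dropped with a warning naming the row numbers.
#' A `peak_id` column is generated as `sample:row` when absent.
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame` peak table.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_peak_table(tab)
}

#' Validate (and complete) a peak table
#'
#' @param tab A data.frame with at least `mz, rt, rtmin, rtmax`.
#' @return The validated table with all optional columns present.
#' @export
validate_peak_table <- function(tab) {
  miss <- setdiff(.peak_table_required, names(tab))
  if (length(miss) > 0L)
    stop("peak table lacks required column(s): ", paste(miss, collapse = ", "))
  for (cn in names(.peak_table_optional))
    if (is.null(tab[[cn]])) tab[[cn]] <- .peak_table_optional[[cn]]
  if (is.null(tab$sample)) tab$sample <- "sample1"
  if (is.null(tab$peak_id))
    tab$peak_id <- paste0(tab$sample, ":", seq_len(nrow(tab)))
  if (anyDuplicated(tab$peak_id))
    stop("peak_id values are not unique")
  bad <- !(tab$rtmin < tab$rt & tab$rt < tab$rtmax)
  bad_mz <- !is.na(tab$mzmin) & !is.na(tab$mzmax) &
    !(tab$mzmin <= tab$mz & tab$mz <= tab$mzmax)
  drop <- which(bad | bad_mz)
  if (length(drop) > 0L) {
    warning("dropping ", length(drop), " invalid peak table row(s): ",
            paste(drop, collapse = ", "))
    tab <- tab[-drop, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Write the characterized peak table
#'
#' Appends the per-peak characteristics and filter decision to the input
#' table and writes it as CSV. Row order is preserved.
#'
#' @param table The input peak table (one row per picked peak).
#' @param chars A data.frame of peak characteristics, one row per input row
#'   (as returned within [characterize_peaks()]).
#' @param decisions A data.frame with columns `keep` (logical) and
#'   `filter_reasons` (character, `;`-separated codes), one row per input row.
#' @param path Output CSV path.
#' @return The combined data.frame, invisibly.
#' @export
write_characterized_table <- function(table, chars, decisions, path) {
  if (nrow(table) != nrow(chars) || nrow(table) != nrow(decisions))
    stop("table, chars and decisions must have one row per peak")
  out <- cbind(table, chars, decisions)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Write a raw run to mzML
#'
#' Writes an in-memory `RawRun` (e.g. from the synthetic benchmark
#' generator) as a centroided MS1 mzML file.
#'
#' @param run A `RawRun`.
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "RawRun"))
  n <- length(run$rt)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(run$spectra, nrow, integer(1)),
    totIonCurrent = vapply(run$spectra, function(m) sum(m[, 2L]), numeric(1)),
    retentionTime = run$rt,
    basePeakMZ = vapply(run$spectra, function(m)
      if (nrow(m)) m[which.max(m[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(m)
      if (nrow(m)) max(m[, 2L]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(m)
      if (nrow(m)) min(m[, 1L]) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(m)
      if (nrow(m)) max(m[, 1L]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(run$spectra), file = path, header = hdr,
                   outformat = "mzml")
  invisible(path)
}
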