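#' Apply the peak quality filters to one characterized peak
#'
#' All criteria are evaluated (not short-circuited) so per-criterion removal
#' statistics can be compiled. Comparisons are strict: a metric exactly at
#' its minimum passes. A peak with no matched apex (`chars = NULL`) or an
#' invalid height fails with reason `no_peak_signature`.
#'
#' Reason codes: `no_peak_signature`, `min_inf_width`, `min_pts`, `min_sn`,
#' `min_intensity`, `tailing_factor`, `min_fwhm`.
#'
#' @param chars One-row characteristics data.frame from
#'   [characterize_peak()], or `NULL` when no apex matched the picked peak.
#' @param cfg A [filter_config()].
#' @return A one-row data.frame: `keep` (logical) and `filter_reasons`
#'   (`;`-separated codes, empty when kept).
#' @export
apply_filters <- function(chars, cfg = filter_config()) {
  reasons <- character(0)
  if (is.null(chars) || !isTRUE(chars$valid)) {
    reasons <- "no_peak_signature"
  } else {
    if (chars$n_inf_points < cfg$min_inf_width)
      reasons <- c(reasons, "min_inf_width")
    if (chars$n_points < cfg$min_pts) reasons <- c(reasons, "min_pts")
    if (chars$sn_cpc < cfg$min_sn) reasons <- c(reasons, "min_sn")
    if (chars$area_cpc < cfg$min_intensity)
      reasons <- c(reasons, "min_intensity")
    if (!is.null(cfg$interval_tf) && is.finite(chars$tailing_factor) &&
        (chars$tailing_factor < cfg$interval_tf[1] ||
         chars$tailing_factor > cfg$interval_tf[2]))
      reasons <- c(reasons, "tailing_factor")
    if (!is.null(cfg$min_fwhm) && is.finite(chars$fwhm) &&
        chars$fwhm < cfg$min_fwhm)
      reasons <- c(reasons, "min_fwhm")
  }
  data.frame(keep = length(reasons) == 0L,
             filter_reasons = paste(reasons, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Partition a peak table by filter decisions
#'
#' @param table Peak table (one row per peak).
#' @param decisions Data.frame of decisions, one row per table row, with
#'   columns `keep` and `filter_reasons`.
#' @return A list with `kept`, `removed` (both order-preserving subsets of
#'   `table`) and `summary` (list: `n`, `n_kept`, `n_removed`,
#'   `removed_fraction`, `reason_counts`).
#' @export
filter_table <- function(table, decisions) {
  if (nrow(table) != nrow(decisions))
    stop("one decision per peak table row required")
  keep <- decisions$keep
  reasons <- unlist(strsplit(decisions$filter_reasons[!keep], ";",
                             fixed = TRUE))
  reasons <- reasons[nzchar(reasons)]
  counts <- if (length(reasons)) as.list(table(reasons)) else list()
  counts <- lapply(counts, as.integer)
  list(kept = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE],
       summary = list(n = nrow(table), n_kept = sum(keep),
                      n_removed = sum(!keep),
                      removed_fraction = if (nrow(table)) mean(!keep) else NA_real_,
                      reason_counts = counts))
}
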