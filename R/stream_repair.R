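#' Detect wireless packet-loss gaps from per-sample timestamps
#'
#' A gap is any consecutive timestamp delta larger than `(1 + tol)` nominal
#' sample periods; the number of lost samples is `round(delta * rate) - 1`.
#'
#' @param timestamps Non-decreasing numeric vector of per-sample times (s).
#' @param nominal_rate Nominal sampling rate in Hz (default 500).
#' @param tol Tolerance in sample periods (default 0.5).
#' @return Data frame (class `gap_list`) with `last_index_before` (sample
#'   index preceding the gap), `lost_samples`, `t_before`, `t_after`.
#' @export
detect_gaps <- function(timestamps, nominal_rate = 500, tol = 0.5) {
  if (is.unsorted(timestamps, strictly = FALSE)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  period <- 1 / nominal_rate
  d <- diff(timestamps)
  at <- which(d > (1 + tol) * period)
  out <- data.frame(
    last_index_before = at,
    lost_samples = as.integer(round(d[at] * nominal_rate)) - 1L,
    t_before = timestamps[at],
    t_after = timestamps[at + 1L]
  )
  class(out) <- c("gap_list", "data.frame")
  out
}

#' Map session-time markers to sample indices of a gappy stream
#'
#' Each marker maps to the sample whose timestamp is nearest its session
#' time. Markers falling inside a detected gap are mapped to the first
#' post-gap sample and flagged `in_gap`; outside gaps the mapping error is at
#' most one sample period.
#'
#' @param marker_times Numeric vector of marker times (s, session clock).
#' @param timestamps Per-sample timestamps of the stream.
#' @param gaps Optional [detect_gaps()] result for the same stream (computed
#'   if `NULL`).
#' @param nominal_rate Nominal rate used when computing `gaps`.
#' @return Data frame with `time_s`, `sample` (1-based index), `in_gap`.
#' @export
align_markers <- function(marker_times, timestamps, gaps = NULL,
                          nominal_rate = 500) {
  if (is.null(gaps)) gaps <- detect_gaps(timestamps, nominal_rate)
  period <- 1 / nominal_rate
  lo <- timestamps[1] - period / 2
  hi <- timestamps[length(timestamps)] + period / 2
  if (any(marker_times < lo | marker_times > hi)) {
    stop("marker outside stream span", call. = FALSE)
  }
  ## nearest timestamp via interval search on midpoints
  mids <- timestamps[-1] - diff(timestamps) / 2
  idx <- findInterval(marker_times, mids) + 1L
  in_gap <- rep(FALSE, length(marker_times))
  if (nrow(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      inside <- marker_times > gaps$t_before[g] + period / 2 &
        marker_times < gaps$t_after[g] - period / 2
      if (any(inside)) {
        idx[inside] <- gaps$last_index_before[g] + 1L
        in_gap[inside] <- TRUE
      }
    }
  }
  data.frame(time_s = marker_times, sample = idx, in_gap = in_gap)
}

#' Write a gap table as the tab-separated repair report
#' @param gaps A [detect_gaps()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gap_table <- function(gaps, path) {
  utils::write.table(as.data.frame(gaps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
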