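#' Write / read event tables in the tab-separated events dialect
#'
#' Events files hold one row per event with the session-clock time and the
#' identifying labels; speech-event files additionally carry `kind`
#' (onset/offset) and `source` (refined/coarse_fallback).
#'
#' @param events Data frame of events.
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the data
#'   frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write the ground-truth word table of a synthetic session
#'
#' Same key columns as the events files plus the true onset/offset times.
#'
#' @param bundle A `session_bundle`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(bundle, path) {
  w <- bundle$truth$words
  utils::write.table(
    w[, c("trial", "word_position", "speaker", "word_length",
          "congruency_speaker", "visual_onset_s", "rt_s",
          "true_onset_s", "true_offset_s", "coarse_onset_s",
          "coarse_offset_s", "lip_smack")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
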