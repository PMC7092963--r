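#' Preprocess an EEG stream and epoch it around events
#'
#' The standard chain: band-pass filter (0.1-30 Hz zero-phase FIR), flag bad
#' channels, remove them, burst-clean the remainder against the artifact-free
#' calibration lead-in, re-reference to averaged mastoids, re-insert bad
#' channels by spherical-spline interpolation, map event times to sample
#' indices (packet-loss aware), and cut baseline-corrected epochs.
#'
#' @param rec An `eeg_recording`.
#' @param events Data frame with `time_s` plus label columns.
#' @param calibration_s `c(start, end)` of the artifact-light calibration
#'   segment (defaults to the first 20 s minus edges).
#' @param cutoff_k Burst-cleaning deviance cutoff.
#' @param window,baseline Epoch windows (s).
#' @param refs Re-reference channels.
#' @param skip_clean Skip burst cleaning (for artifact-free synthesis).
#' @param detect_bad Run bad-channel detection (disable for degenerate
#'   noise-free synthetic data where every channel looks flat).
#' @return An `epoch_set`; attributes `"bad_channels"`, `"gaps"`,
#'   `"n_windows_cleaned"`, `"in_gap_events"`.
#' @export
preprocess_eeg <- function(rec, events, calibration_s = c(1, 19),
                           cutoff_k = 8, window = c(-0.5, 1.5),
                           baseline = c(-0.1, 0), refs = c("TP9", "TP10"),
                           skip_clean = FALSE, detect_bad = TRUE) {
  gaps <- detect_gaps(rec$timestamps, rec$rate)
  rec <- bandpass(rec)
  bad <- if (detect_bad) {
    tryCatch(detect_bad_channels(rec), error = function(e) character(0))
  } else {
    character(0)
  }
  bad <- setdiff(bad, refs)  # mastoid references must survive
  n_cleaned <- 0L
  if (length(bad)) {
    keep <- !(rec$labels %in% bad)
    sub <- rec
    sub$data <- rec$data[keep, , drop = FALSE]
    sub$labels <- rec$labels[keep]
  } else {
    sub <- rec
  }
  if (!skip_clean) {
    sub <- clean_bursts(sub, calibration_s, cutoff_k = cutoff_k)
    n_cleaned <- attr(sub, "n_windows_cleaned") %||% 0L
  }
  sub <- rereference(sub, refs)
  if (length(bad)) {
    full <- matrix(0, length(rec$labels), ncol(sub$data),
                   dimnames = list(rec$labels, NULL))
    full[sub$labels, ] <- sub$data
    sub$data <- full
    sub$labels <- rec$labels
    sub <- interpolate_channels(sub, bad)
  }
  al <- align_markers(events$time_s, sub$timestamps, gaps, sub$rate)
  events$sample <- al$sample
  events$in_gap <- al$in_gap
  ep <- epoch_recording(sub, events[!events$in_gap, , drop = FALSE],
                        window, baseline, gaps)
  attr(ep, "bad_channels") <- bad
  attr(ep, "gaps") <- gaps
  attr(ep, "n_windows_cleaned") <- n_cleaned
  attr(ep, "in_gap_events") <- sum(al$in_gap)
  ep
}

#' Heard-word events of one participant
#'
#' Builds the event table for epoching: the partner's speech onsets, labelled
#' with the listener's own congruency. Uses refined speech events when
#' given, otherwise the coarse voice-key markers.
#'
#' @param bundle A `session_bundle`.
#' @param participant Listener id (1 or 2).
#' @param speech_events Optional refined events from
#'   [refine_session_events()].
#' @param use_truth Lock epochs to the simulator's ground-truth onsets; the
#'   default does so when no refined events are given and the bundle carries
#'   no audio (coarse voice-key markers are quantized up to 100 ms late and
#'   would smear the evoked responses).
#' @return Data frame: `time_s`, `trial`, `word_position`, `congruency`
#'   (listener's), `event_type = "heard"`.
#' @export
heard_word_events <- function(bundle, participant, speech_events = NULL,
                              use_truth = is.null(speech_events) &&
                                is.null(bundle$audio)) {
  if (is.null(speech_events) && use_truth) {
    src <- bundle$truth$words[bundle$truth$words$speaker != participant, ]
    out <- data.frame(time_s = src$true_onset_s, trial = src$trial,
                      word_position = src$word_position)
  } else if (is.null(speech_events)) {
    ev <- bundle$events
    src <- ev[ev$event_type == "speech_onset_coarse" &
                ev$participant != participant, ]
    out <- data.frame(time_s = src$time_s, trial = src$trial,
                      word_position = src$word_position)
  } else {
    src <- speech_events[speech_events$kind == "onset" &
                           speech_events$participant != participant, ]
    out <- data.frame(time_s = src$time_s, trial = src$trial,
                      word_position = src$word_position)
  }
  cong_col <- paste0("congruency_p", participant)
  out$congruency <- bundle$plan[[cong_col]][match(out$trial,
                                                  bundle$plan$trial_index)]
  out$event_type <- "heard"
  out[order(out$time_s), ]
}

#' Subset an epoch set by a logical/integer selector on its labels
#'
#' @param ep An `epoch_set`.
#' @param sel Logical or integer selector over epochs.
#' @return The subset `epoch_set`.
#' @export
subset_epochs <- function(ep, sel) {
  if (is.logical(sel)) sel <- which(sel)
  ep$epochs <- ep$epochs[sel, , , drop = FALSE]
  ep$labels <- ep$labels[sel, , drop = FALSE]
  ep
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters with one master seed from which each
#' stage derives its own seed via [derive_seed()] (stage counters: 1 plan,
#' 2 synthesis, 3 count matching), so stages can be re-run in isolation.
#'
#' @param n_trials,frac_incongruent,incongruent_split Design parameters.
#' @param master_seed Master seed.
#' @param params A [synth_params()].
#' @param onset_cfg An [onset_config()].
#' @param ride_cfg A [ride_config()].
#' @param use_refined_onsets Refine onsets from audio (requires
#'   `params$make_audio`); otherwise coarse markers are used for RTs and
#'   ground-truth onsets for ERPs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_trials = 60, frac_incongruent = 0.25,
                            incongruent_split = NULL, master_seed = 1,
                            params = synth_params(),
                            onset_cfg = onset_config(),
                            ride_cfg = ride_config(),
                            use_refined_onsets = TRUE) {
  structure(list(
    spec = design_spec(n_trials, frac_incongruent,
                       incongruent_split = incongruent_split),
    master_seed = master_seed, params = params, onset_cfg = onset_cfg,
    ride_cfg = ride_cfg, use_refined_onsets = use_refined_onsets
  ), class = "pipeline_config")
}

#' Run the full dyadic analysis pipeline on one synthetic session
#'
#' simulate -> refine speech events -> repair/align -> preprocess/epoch ->
#' latency-corrected ERPs -> window statistics -> RT model, with a
#' consolidated report. Fully reproducible from the configuration and its
#' master seed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report`: `plan_counts`,
#'   `onset_metrics`, `gap_report`, `epoch_counts`, `erp` (per participant:
#'   congruent/incongruent reconstructed CW ERPs and window-mean
#'   differences), `rt` (exclusion report and GLMM fits when estimable),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  plan <- build_trial_plan(config$spec,
                           sentence_lexicon(config$spec$n_trials),
                           seed = derive_seed(config$master_seed, 1))
  stopifnot(length(validate_plan(plan)) == 0)
  bundle <- synth_session(plan, config$params,
                          seed = derive_seed(config$master_seed, 2))

  speech <- NULL
  onset_metrics <- NULL
  if (config$use_refined_onsets && !is.null(bundle$audio)) {
    speech <- refine_session_events(bundle, config$onset_cfg)
    onset_metrics <- score_events(speech, bundle$truth$words)
    onset_metrics$errors_ms <- NULL
  }

  gap_report <- lapply(Filter(Negate(is.null), bundle$eeg), function(r) {
    detect_gaps(r$timestamps, r$rate)
  })

  erp <- list()
  epoch_counts <- list()
  win <- window_spec()
  for (p in config$params$eeg_participants) {
    rec <- bundle$eeg[[paste0("p", p)]]
    if (is.null(rec)) next
    ev <- heard_word_events(bundle, p, speech)
    ep <- preprocess_eeg(rec, ev,
                         calibration_s = c(1, config$params$calibration_s - 1))
    ep <- reject_3sd(ep)
    is_cw <- ep$labels$word_position == 8
    cong <- subset_epochs(ep, is_cw & ep$labels$congruency == "congruent")
    inc <- subset_epochs(ep, is_cw & ep$labels$congruency == "incongruent")
    epoch_counts[[paste0("p", p)]] <- c(
      heard = dim(ep$epochs)[1], cw_congruent = dim(cong$epochs)[1],
      cw_incongruent = dim(inc$epochs)[1],
      rejected = nrow(ep$rejected %||% data.frame()))
    if (dim(cong$epochs)[1] >= 10 && dim(inc$epochs)[1] >= 10) {
      mm <- match_counts(cong, inc, seed = derive_seed(config$master_seed, 3))
      rc <- ride_decompose(mm$a, config$ride_cfg)
      ri <- ride_decompose(mm$b, config$ride_cfg)
      ec <- reconstruct_erp(rc)
      ei <- reconstruct_erp(ri)
      diffs <- vapply(c("P200", "N400", "P600"), function(cp) {
        chs <- config$params$components$center[
          match(cp, config$params$components$name)]
        window_means(ei, win$windows_ms[[cp]], chs, rc$times) -
          window_means(ec, win$windows_ms[[cp]], chs, rc$times)
      }, numeric(1))
      erp[[paste0("p", p)]] <- list(congruent = ec, incongruent = ei,
                                    window_mean_diffs_uV = diffs,
                                    n_per_condition = dim(mm$a$epochs)[1])
    }
  }

  rt <- NULL
  if (!is.null(speech) || TRUE) {
    vis <- bundle$events[bundle$events$event_type == "visual", ]
    sev <- if (!is.null(speech)) {
      speech
    } else {
      ev <- bundle$events[bundle$events$event_type %in%
                            c("speech_onset_coarse", "speech_offset_coarse"), ]
      data.frame(participant = ev$participant, trial = ev$trial,
                 word_position = ev$word_position,
                 kind = ifelse(ev$event_type == "speech_onset_coarse",
                               "onset", "offset"),
                 time_s = ev$time_s, source = "coarse_fallback")
    }
    tab <- extract_rts(sev, vis, plan)
    fl <- filter_rts(tab)
    fits <- list()
    for (sq in c("cw_odd", "cw_even")) {
      fits[[sq]] <- tryCatch({
        full <- fit_rt_glmm(fl$table, sq)
        red <- fit_rt_glmm(fl$table, sq, include_congruency = FALSE)
        list(fit = full, lrt_congruency = lrt(full, red))
      }, error = function(e) list(error = conditionMessage(e)))
    }
    rt <- list(exclusion_report = fl$report, fits = fits)
  }

  structure(list(
    plan_counts = plan_counts(plan), onset_metrics = onset_metrics,
    gap_report = gap_report, epoch_counts = epoch_counts, erp = erp,
    rt = rt, config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("plan counts:\n"); print(x$plan_counts)
  if (!is.null(x$onset_metrics)) {
    cat(sprintf("onset refinement: bias %.2f ms, median |err| %.2f ms, fallback %.1f%%\n",
                x$onset_metrics$bias_ms, x$onset_metrics$median_abs_ms,
                100 * x$onset_metrics$fallback_rate))
  }
  for (p in names(x$erp)) {
    cat(sprintf("%s CW window-mean differences (incongruent - congruent, uV):\n", p))
    print(round(x$erp[[p]]$window_mean_diffs_uV, 2))
  }
  invisible(x)
}
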