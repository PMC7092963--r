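#' Parameters of the synthetic dyadic session generator
#'
#' Collects every constant the simulator needs. Defaults encode the study
#' conditions of the paradigm: 44.1 kHz stereo audio, two 500 Hz EEG streams
#' over the 24-signal-channel cap, prime 2.5 s / fixation 0.5 s / 1.5 s
#' inter-trial timing, ~0.54 s mean word duration, ~0.49 s mean
#' visual-to-speech latency, a 100 ms voice-key grid, and event-related
#' components N100/P200/N400/P600 with peak latencies 114/250/480/600 ms.
#' Incongruent heard critical words receive additive amplitude deltas
#' (+2 microvolt P200, -3 microvolt N400, +2 microvolt P600); the N100 of the
#' first heard word of a trial is scaled by `first_word_n100_gain`.
#'
#' Background EEG is 1/f^2 noise plus 10 Hz alpha; amplitudes are fixed so
#' that planted effects of a few microvolts are recoverable from roughly 40
#' trials per condition, matching the design's trial counts.
#'
#' @param n_trials Unused here (the plan determines trials); kept for clarity.
#' @param components Data frame of ERP kernels: `name`, `latency_ms`,
#'   `width_ms` (Gaussian SD), `amplitude_uV` (signed peak), `center`
#'   (electrode at which the topographic weight is 1), `spread` (topography
#'   width on the unit sphere).
#' @param congruency_delta_uV Named additive deltas applied to heard
#'   incongruent CWs (positive = more positive-going).
#' @param first_word_n100_gain Multiplier on the N100 amplitude of each
#'   trial's first heard word.
#' @param latency_jitter_ms Named per-component SD of single-trial latency
#'   jitter; 0 disables jitter for that component.
#' @param rt_model Inverse-link gamma model for reaction times: `intercept`
#'   (1/s), `congruency` (link-scale shift for the speaker's incongruent
#'   trials), `first_word` (link shift for word 1), `position_slope` (link
#'   shift per word position, centred at word 7), `word_length` (link shift
#'   per letter, centred at 5 letters), `participant_sd` (SD of random
#'   participant intercepts), `shape` (gamma shape).
#' @param noise `background_sd_uV` (bandlimited SD of the 1/f^2 floor),
#'   `alpha_amp_uV`, `alpha_freq`.
#' @param artifacts `blink_rate_per_min`, `blink_amp_uV`, `emg_amp_uV` (jaw
#'   EMG during own speech), `lip_smack_prob` (per word).
#' @param timing `prime_s`, `fixation_s`, `iti_s`, `word_base_s` +
#'   `word_per_letter_s` (median duration model), `word_sdlog` (lognormal
#'   spread), `attack_s`/`decay_s` (envelope ramps), `onset_frac` (envelope
#'   fraction defining true onset/offset).
#' @param marker_grid_s Voice-key quantization grid (s).
#' @param packet_loss `NULL`, a fraction of samples to drop in random gaps,
#'   or a list of `c(start_s, duration_s)` intervals.
#' @param calibration_s Artifact-free lead-in before the first trial, used to
#'   calibrate burst cleaning.
#' @param make_audio,eeg_participants Generation switches: audio on/off and
#'   which participants get an EEG stream (subset of `1:2`); both streams and
#'   the audio share one session clock regardless.
#' @param audio_rate,eeg_rate,channels Sampling rates (Hz) and channel labels.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(
    audio_rate = 44100,
    eeg_rate = 500,
    channels = wbw_montage,
    components = data.frame(
      name = c("N100", "P200", "N400", "P600"),
      latency_ms = c(114, 250, 480, 600),
      width_ms = c(20, 35, 50, 55),
      amplitude_uV = c(-2, 3, -4, 2.5),
      center = c("Fz", "Cz", "CPz", "Pz"),
      spread = 0.6,
      stringsAsFactors = FALSE),
    congruency_delta_uV = c(P200 = 2, N400 = -3, P600 = 2),
    first_word_n100_gain = 2,
    latency_jitter_ms = c(N100 = 0, P200 = 0, N400 = 0, P600 = 0),
    rt_model = list(intercept = 2.04, congruency = 0.022, first_word = -0.5,
                    position_slope = 0, word_length = -0.015,
                    participant_sd = 0.08, shape = 30),
    noise = list(background_sd_uV = 1.5, alpha_amp_uV = 1, alpha_freq = 10),
    artifacts = list(blink_rate_per_min = 15, blink_amp_uV = 200,
                     emg_amp_uV = 15, lip_smack_prob = 0.05),
    timing = list(prime_s = 2.5, fixation_s = 0.5, iti_s = 1.5,
                  word_base_s = 0.30, word_per_letter_s = 0.045,
                  word_sdlog = 0.12, attack_s = 0.010, decay_s = 0.030,
                  onset_frac = 0.1),
    marker_grid_s = 0.1,
    packet_loss = NULL,
    calibration_s = 20,
    make_audio = TRUE,
    eeg_participants = c(1, 2)) {
  stopifnot(audio_rate > 0, eeg_rate > 0, length(channels) >= 1,
            marker_grid_s > 0)
  if (any(components$width_ms <= 0)) stop("component widths must be positive")
  dn <- congruency_delta_uV
  if (!is.null(dn["P200"]) && !is.na(dn["P200"]) && dn["P200"] < 0)
    stop("P200 congruency delta must be >= 0 (incongruent more positive)")
  if (!is.na(dn["N400"]) && dn["N400"] > 0)
    stop("N400 congruency delta must be <= 0 (incongruent more negative)")
  if (!is.na(dn["P600"]) && dn["P600"] < 0)
    stop("P600 congruency delta must be >= 0 (incongruent more positive)")
  structure(list(
    audio_rate = audio_rate, eeg_rate = eeg_rate, channels = channels,
    components = components, congruency_delta_uV = congruency_delta_uV,
    first_word_n100_gain = first_word_n100_gain,
    latency_jitter_ms = latency_jitter_ms, rt_model = rt_model,
    noise = noise, artifacts = artifacts, timing = timing,
    marker_grid_s = marker_grid_s, packet_loss = packet_loss,
    calibration_s = calibration_s, make_audio = make_audio,
    eeg_participants = eeg_participants
  ), class = "synth_params")
}
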