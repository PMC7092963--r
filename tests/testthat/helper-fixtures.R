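## Shared fixture builders. Expensive objects are cached per test file run
## (helpers are sourced once per file) via a local environment.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

## small dyadic plan: 6 trials, 2 incongruent per participant (1 perceiving,
## 1 speaking)
fx_plan_small <- function(n = 6) {
  spec <- design_spec(n_trials = n, frac_incongruent = 2 / n,
                      incongruent_split = c(1, 1))
  build_trial_plan(spec, sentence_lexicon(n), seed = 7)
}

## quiet synth params: no artifacts, optionally no noise / no audio
fx_params <- function(audio = TRUE, eeg = c(1, 2), noise = TRUE,
                      jitter = c(N100 = 0, P200 = 0, N400 = 0, P600 = 0),
                      lip_smack = 0, ...) {
  synth_params(
    make_audio = audio, eeg_participants = eeg,
    noise = if (noise) {
      list(background_sd_uV = 1.5, alpha_amp_uV = 1, alpha_freq = 10)
    } else {
      list(background_sd_uV = 0, alpha_amp_uV = 0, alpha_freq = 10)
    },
    latency_jitter_ms = jitter,
    artifacts = list(blink_rate_per_min = 0, blink_amp_uV = 0,
                     emg_amp_uV = 0, lip_smack_prob = lip_smack),
    ...
  )
}

## a clean audio-only session shared by the speech-event tests
fx_audio_session <- function() {
  fx_cached("audio_session", function() {
    synth_session(fx_plan_small(), fx_params(eeg = integer(0)), seed = 11)
  })
}

## an EEG-only session (both participants) shared by erp tests
fx_eeg_session <- function() {
  fx_cached("eeg_session", function() {
    spec <- design_spec(n_trials = 12, frac_incongruent = 0.25,
                        incongruent_split = c(2, 1))
    plan <- build_trial_plan(spec, sentence_lexicon(12), seed = 5)
    synth_session(plan, fx_params(audio = FALSE), seed = 21)
  })
}

## a synthetic eeg_recording with spatially smooth content
fx_recording <- function(n_s = 60, seed = 3, rate = 500) {
  n <- n_s * rate
  with_seed <- wordbyword:::with_seed
  with_seed(seed, {
    W <- vapply(1:8, function(k) {
      topography_weights(sample(wbw_montage, 1), stats::runif(1, 0.5, 1))
    }, numeric(24))
    data <- W %*% matrix(stats::rnorm(8 * n), 8) +
      0.5 * matrix(stats::rnorm(24 * n), 24)
    rownames(data) <- wbw_montage
    structure(list(data = data, labels = wbw_montage, rate = rate,
                   timestamps = (seq_len(n) - 1) / rate, ref = "FCz"),
              class = "eeg_recording")
  })
}

## heard-word epochs pooled over both participants of a session
fx_heard_epochs <- function(bundle, skip_clean = TRUE, detect_bad = FALSE) {
  eps <- lapply(bundle$params$eeg_participants, function(p) {
    preprocess_eeg(bundle$eeg[[paste0("p", p)]],
                   heard_word_events(bundle, p),
                   calibration_s = c(1, bundle$params$calibration_s - 1),
                   skip_clean = skip_clean, detect_bad = detect_bad)
  })
  combine_epochs(eps)
}
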