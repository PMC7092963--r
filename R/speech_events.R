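#' Configuration for offline speech onset/offset refinement
#'
#' Parameters of the offline refinement that turns coarse 100 ms voice-key
#' markers into precise speech events: the audio is epoched (-0.5 to +1 s)
#' around the coarse marker, highpass filtered at 35 Hz to erase
#' low-frequency fluctuations, downsampled to 1470 Hz; an amplitude envelope
#' (moving-average filter length 300) and the first two mel-cepstral
#' coefficient traces are computed, and abrupt changes in the RMS of the
#' downsampled signal are located by penalized change-in-mean segmentation.
#' A candidate changepoint is accepted only when the envelope and at least
#' one cepstral trace change concurrently, which rejects lip smacks and
#' other transient artifacts.
#'
#' The printed 730 Hz (envelope) and 600 Hz (cepstrum) smoothing cutoffs sit
#' at or near the 735 Hz Nyquist of the 1470 Hz trace; they are clamped to
#' 0.95 x Nyquist, making them near-pass-through smoothers, while the config
#' retains the nominal numbers.
#'
#' @param epoch_window Window around the coarse marker, seconds.
#' @param highpass_hz Audio highpass cutoff.
#' @param downsample_rate Analysis rate (44100 / 30).
#' @param envelope_filter_len Moving-average length (samples at
#'   `downsample_rate`) for the validation envelope.
#' @param envelope_lowpass_hz,cepstral_lowpass_hz Nominal smoothing cutoffs,
#'   clamped to 0.95 x Nyquist at application time.
#' @param n_cepstral Number of mel-cepstral coefficient traces (first two).
#' @param cep_frame,cep_hop Mel-cepstrum frame length and hop (samples at
#'   `downsample_rate`).
#' @param rms_window Sliding RMS window (samples).
#' @param penalty Changepoint penalty; `NULL` selects
#'   `penalty_factor * var(trace) * log(n)`.
#' @param penalty_factor Multiplier for the automatic penalty.
#' @param min_seg Minimum segment length (samples) for the segmentation.
#' @param validation_window_s Tolerance within which envelope and cepstral
#'   changes must co-occur with an RMS changepoint.
#' @param min_rel_rise Minimum envelope rise, as a fraction of the epoch
#'   envelope peak, for a change to count as "apparent".
#' @param cep_change_frac Minimum cepstral mean shift across the candidate,
#'   as a fraction of the trace SD.
#' @param onset_frac Envelope fraction whose crossing defines the refined
#'   onset time (matches the ground-truth onset definition).
#' @param fine_env_len Short moving-average length (samples) for the
#'   threshold-crossing envelope.
#' @return Object of class `onset_config`.
#' @export
onset_config <- function(epoch_window = c(-0.5, 1.0), highpass_hz = 35,
                         downsample_rate = 1470, envelope_filter_len = 300,
                         envelope_lowpass_hz = 730, cepstral_lowpass_hz = 600,
                         n_cepstral = 2, cep_frame = 128, cep_hop = 16,
                         rms_window = 32, penalty = NULL, penalty_factor = 5,
                         min_seg = 15, validation_window_s = 0.030,
                         min_rel_rise = 0.2, cep_change_frac = 0.25,
                         onset_frac = 0.1, fine_env_len = 12) {
  stopifnot(epoch_window[1] < 0, epoch_window[2] > 0,
            validation_window_s > 0, min_rel_rise > 0)
  structure(list(
    epoch_window = epoch_window, highpass_hz = highpass_hz,
    downsample_rate = downsample_rate,
    envelope_filter_len = envelope_filter_len,
    envelope_lowpass_hz = envelope_lowpass_hz,
    cepstral_lowpass_hz = cepstral_lowpass_hz, n_cepstral = n_cepstral,
    cep_frame = cep_frame, cep_hop = cep_hop, rms_window = rms_window,
    penalty = penalty, penalty_factor = penalty_factor, min_seg = min_seg,
    validation_window_s = validation_window_s, min_rel_rise = min_rel_rise,
    cep_change_frac = cep_change_frac, onset_frac = onset_frac,
    fine_env_len = fine_env_len
  ), class = "onset_config")
}

## windowed-sinc FIR lowpass kernel (Hann window, odd length)
.fir_lowpass_kernel <- function(len, fc, fs) {
  stopifnot(len %% 2 == 1)
  m <- (len - 1) / 2
  n <- seq(-m, m)
  h <- 2 * fc / fs * sinc_(2 * fc / fs * n)
  w <- 0.5 + 0.5 * cos(pi * n / (m + 1))
  h <- h * w
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## zero-phase FIR application: FFT convolution, group delay removed
.fir_apply <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1) / 2
  xp <- c(rev(x[seq_len(min(m, n))]), x, rev(x[seq.int(n - min(m, n) + 1, n)]))
  y <- signal::fftfilt(h, c(xp, numeric(length(h))))
  y[(m + min(m, n)) + seq_len(n)]
}

## highpass via spectral inversion of a lowpass kernel
.fir_highpass_kernel <- function(len, fc, fs) {
  h <- -.fir_lowpass_kernel(len, fc, fs)
  h[(len + 1) / 2] <- h[(len + 1) / 2] + 1
  h
}

## near-pass-through smoother standing in for a lowpass whose nominal cutoff
## is clamped to 0.95 x Nyquist
.clamped_lowpass <- function(x, nominal_hz, fs) {
  w <- min(nominal_hz / (fs / 2), 0.95)
  bf <- signal::butter(2, w)
  as.numeric(signal::filtfilt(bf, x))
}

## mel filterbank cepstral coefficient traces (frames -> interpolated)
.mel_cepstra <- function(x, fs, frame, hop, n_coef) {
  n <- length(x)
  if (n < frame) stop("epoch shorter than a cepstral frame", call. = FALSE)
  starts <- seq(1, n - frame + 1, by = hop)
  nmel <- 16
  ## mel filterbank up to Nyquist
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(fs / 2), length.out = nmel + 2))
  nfft <- frame
  freqs <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  fb <- matrix(0, nmel, length(freqs))
  for (j in seq_len(nmel)) {
    lo <- edges[j]; cen <- edges[j + 1]; hi <- edges[j + 2]
    up <- freqs >= lo & freqs <= cen
    dn <- freqs > cen & freqs <= hi
    fb[j, up] <- (freqs[up] - lo) / max(cen - lo, 1e-9)
    fb[j, dn] <- (hi - freqs[dn]) / max(hi - cen, 1e-9)
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(frame) / (frame + 1))
  cep <- matrix(0, length(starts), n_coef)
  for (i in seq_along(starts)) {
    seg <- x[starts[i] + seq_len(frame) - 1] * win
    sp <- abs(stats::fft(seg))[seq_len(nfft / 2 + 1)]^2
    loge <- log(as.numeric(fb %*% sp) + 1e-10)
    ## DCT-II, coefficients 1..n_coef (after the energy term)
    for (q in seq_len(n_coef)) {
      cep[i, q] <- sum(loge * cos(pi * q * (seq_len(nmel) - 0.5) / nmel))
    }
  }
  centers <- starts + (frame - 1) / 2
  out <- matrix(0, n, n_coef)
  for (q in seq_len(n_coef)) {
    out[, q] <- stats::approx(centers, cep[, q], xout = seq_len(n),
                              rule = 2)$y
  }
  out
}

#' Compute onset-detection features for one audio epoch
#'
#' Highpass -> downsample -> envelope, mel-cepstral traces and sliding RMS,
#' all on the 1470 Hz time base with epoch-relative indices. Deterministic.
#'
#' @param epoch Numeric audio vector sampled at `audio_rate`, covering the
#'   configured epoch window.
#' @param config An [onset_config()].
#' @param audio_rate Input sampling rate (Hz).
#' @return List of class `feature_set`: `signal`, `envelope`, `cepstra`
#'   (matrix, one column per trace), `rms`, `fine_env`, `rate`, `n`.
#' @export
compute_features <- function(epoch, config = onset_config(),
                             audio_rate = 44100) {
  need <- round((config$epoch_window[2] - config$epoch_window[1]) * audio_rate)
  if (length(epoch) < need) {
    stop("epoch shorter than the configured window", call. = FALSE)
  }
  dec <- round(audio_rate / config$downsample_rate)
  rds <- audio_rate / dec

  hp <- .fir_highpass_kernel(401, config$highpass_hz, audio_rate)
  x <- .fir_apply(epoch, hp)
  aa <- .fir_lowpass_kernel(601, 0.45 * rds, audio_rate)
  x <- .fir_apply(x, aa)
  x <- x[seq(1, length(x), by = dec)]
  n <- length(x)

  env <- moving_average(abs(x), config$envelope_filter_len)
  env <- .clamped_lowpass(env, config$envelope_lowpass_hz, rds)
  cep <- .mel_cepstra(x, rds, config$cep_frame, config$cep_hop,
                      config$n_cepstral)
  for (q in seq_len(ncol(cep))) {
    cep[, q] <- .clamped_lowpass(cep[, q], config$cepstral_lowpass_hz, rds)
  }
  rms <- sqrt(pmax(moving_average(x^2, config$rms_window), 0))
  fine <- moving_average(abs(x), config$fine_env_len)

  structure(list(signal = x, envelope = env, cepstra = cep, rms = rms,
                 fine_env = fine, rate = rds, n = n),
            class = "feature_set")
}

#' Penalized change-in-mean segmentation of a trace
#'
#' PELT-style exact minimization of segment-wise squared error plus a
#' per-changepoint penalty; returns the optimal changepoint indices (the
#' last sample of each left segment), sorted ascending. An empty result is
#' valid (no abrupt change found).
#'
#' @param x Numeric trace (e.g. the sliding RMS of the downsampled audio).
#' @param penalty Positive scalar; `NULL` selects
#'   `penalty_factor * var(x) * log(n)`.
#' @param min_seg Minimum segment length in samples.
#' @param penalty_factor Used only when `penalty` is `NULL`.
#' @return Integer vector of changepoint indices (possibly empty).
#' @export
detect_rms_changepoints <- function(x, penalty = NULL, min_seg = 15,
                                    penalty_factor = 5) {
  n <- length(x)
  if (n == 0) stop("empty trace", call. = FALSE)
  if (n < 2 * min_seg) return(integer(0))
  if (is.null(penalty)) {
    penalty <- penalty_factor * stats::var(x) * log(n)
    if (!is.finite(penalty) || penalty <= 0) return(integer(0))
  }
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {
    ## cost of segment (a+1)..b
    (S2[b + 1] - S2[a + 1]) - (S[b + 1] - S[a + 1])^2 / (b - a)
  }
  F <- rep(Inf, n + 1)
  F[1] <- -penalty
  last <- integer(n + 1)
  R <- 0L
  for (t in seq.int(min_seg, n)) {
    cand <- R[t - R >= min_seg]
    if (!length(cand)) next
    vals <- F[cand + 1L] + (S2[t + 1L] - S2[cand + 1L]) -
      (S[t + 1L] - S[cand + 1L])^2 / (t - cand) + penalty
    i <- which.min(vals)
    F[t + 1L] <- vals[i]
    last[t + 1L] <- cand[i]
    keep <- cand[vals - penalty <= F[t + 1L]]
    ## indices too recent to have been evaluated stay in the candidate set
    R <- c(keep, R[t - R < min_seg], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0 && F[t + 1L] < Inf) {
    a <- last[t + 1L]
    if (a == 0) break
    cps <- c(a, cps)
    t <- a
  }
  cps
}

#' Validate RMS changepoint candidates against envelope and cepstrum
#'
#' Accepts the earliest candidate at which, within the validation window,
#' the envelope rises by at least `min_rel_rise` of its epoch peak AND at
#' least one mel-cepstral trace shifts concurrently. Transient clicks (lip
#' smacks) produce no sustained envelope rise and are rejected.
#'
#' @param candidates Integer indices from [detect_rms_changepoints()].
#' @param features A [compute_features()] result.
#' @param config An [onset_config()].
#' @return The accepted candidate index, or `NULL` if none passes.
#' @export
validate_candidates <- function(candidates, features,
                                config = onset_config()) {
  if (length(candidates) == 0) return(NULL)
  n <- features$n
  W <- max(2L, round(config$validation_window_s * features$rate))
  peak <- max(features$envelope)
  if (peak <= 0) return(NULL)
  for (k in sort(candidates)) {
    pre <- max(1, k - W):k
    post <- k:min(n, k + W)
    rise <- max(features$envelope[post]) - min(features$envelope[pre])
    if (rise < config$min_rel_rise * peak) next
    cep_ok <- FALSE
    for (q in seq_len(ncol(features$cepstra))) {
      tr <- features$cepstra[, q]
      shift <- abs(mean(tr[post]) - mean(tr[pre]))
      if (shift >= config$cep_change_frac * stats::sd(tr)) {
        cep_ok <- TRUE
        break
      }
    }
    if (cep_ok) return(k)
  }
  NULL
}

## core refinement on an already-extracted epoch (marker at -epoch_window[1])
.refine_in_epoch <- function(seg, config, audio_rate) {
  feats <- compute_features(seg, config, audio_rate)
  cands <- detect_rms_changepoints(feats$rms, config$penalty, config$min_seg,
                                   config$penalty_factor)
  acc <- validate_candidates(cands, feats, config)
  if (is.null(acc)) return(list(accepted = FALSE, idx = NA_real_))
  ## refine to the envelope threshold crossing nearest the candidate
  fine <- feats$fine_env
  th <- config$onset_frac * max(fine)
  up <- which(fine[-1] >= th & fine[-length(fine)] < th) + 1L
  if (length(up)) {
    W2 <- round(2 * config$validation_window_s * feats$rate)
    near <- up[abs(up - acc) <= W2]
    if (length(near)) acc <- near[which.min(abs(near - acc))]
  }
  list(accepted = TRUE, idx = acc, rate = feats$rate)
}

#' Refine a coarse voice-key onset marker from the audio
#'
#' Epochs the audio around the coarse marker, computes the feature set, finds
#' RMS changepoints, validates them against envelope and cepstrum, and
#' converts the accepted change to session time. When no candidate passes,
#' the coarse marker is returned flagged `source = "coarse_fallback"`.
#'
#' @param audio Numeric vector: one participant's audio channel.
#' @param coarse_time Coarse marker time (s, session clock).
#' @param config An [onset_config()].
#' @param audio_rate Sampling rate of `audio`.
#' @return One-row data frame: `kind`, `time_s`, `source`.
#' @export
refine_onset <- function(audio, coarse_time, config = onset_config(),
                         audio_rate = 44100) {
  n <- length(audio)
  if (coarse_time < 0 || coarse_time > n / audio_rate) {
    stop("marker outside audio span", call. = FALSE)
  }
  i0 <- round((coarse_time + config$epoch_window[1]) * audio_rate) + 1
  i1 <- round((coarse_time + config$epoch_window[2]) * audio_rate)
  if (i0 < 1 || i1 > n) {
    stop("epoch window around marker extends beyond the audio", call. = FALSE)
  }
  res <- .refine_in_epoch(audio[i0:i1], config, audio_rate)
  if (!res$accepted) {
    return(data.frame(kind = "onset", time_s = coarse_time,
                      source = "coarse_fallback", stringsAsFactors = FALSE))
  }
  t <- (coarse_time + config$epoch_window[1]) + (res$idx - 1) / res$rate
  data.frame(kind = "onset", time_s = t, source = "refined",
             stringsAsFactors = FALSE)
}

#' Refine a coarse voice-key offset marker (time-reversed onset procedure)
#'
#' The epoch around the coarse offset marker is time-reversed, the onset
#' procedure is applied, and the detected time is mapped back to forward
#' time.
#'
#' @inheritParams refine_onset
#' @return One-row data frame: `kind = "offset"`, `time_s`, `source`.
#' @export
refine_offset <- function(audio, coarse_time, config = onset_config(),
                          audio_rate = 44100) {
  n <- length(audio)
  if (coarse_time < 0 || coarse_time > n / audio_rate) {
    stop("marker outside audio span", call. = FALSE)
  }
  ## in reversed time the marker must sit at -epoch_window[1] from the start
  i0 <- round((coarse_time - config$epoch_window[2]) * audio_rate) + 1
  i1 <- round((coarse_time - config$epoch_window[1]) * audio_rate)
  if (i0 < 1 || i1 > n) {
    stop("epoch window around marker extends beyond the audio", call. = FALSE)
  }
  res <- .refine_in_epoch(rev(audio[i0:i1]), config, audio_rate)
  if (!res$accepted) {
    return(data.frame(kind = "offset", time_s = coarse_time,
                      source = "coarse_fallback", stringsAsFactors = FALSE))
  }
  t <- (coarse_time - config$epoch_window[1]) - (res$idx - 1) / res$rate
  data.frame(kind = "offset", time_s = t, source = "refined",
             stringsAsFactors = FALSE)
}

#' Refine all coarse speech markers of a synthetic session
#'
#' Applies [refine_onset()] and [refine_offset()] to every coarse voice-key
#' marker in a session's marker stream, using the speaking participant's
#' audio channel.
#'
#' @param bundle A `session_bundle` with audio.
#' @param config An [onset_config()].
#' @param kinds Which events to refine (`"onset"`, `"offset"` or both).
#' @return Data frame of speech events: `participant`, `trial`,
#'   `word_position`, `kind`, `time_s`, `source`.
#' @export
refine_session_events <- function(bundle, config = onset_config(),
                                  kinds = c("onset", "offset")) {
  if (is.null(bundle$audio)) stop("session bundle has no audio")
  wanted <- paste0("speech_", kinds, "_coarse")
  ev <- bundle$events
  out <- vector("list", nrow(ev))
  k <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (!e$event_type %in% wanted) {
      next
    }
    chan <- bundle$audio[[paste0("p", e$participant)]]
    r <- if (e$event_type == "speech_onset_coarse") {
      refine_onset(chan, e$time_s, config, bundle$audio$rate)
    } else {
      refine_offset(chan, e$time_s, config, bundle$audio$rate)
    }
    k <- k + 1L
    out[[k]] <- cbind(
      data.frame(participant = e$participant, trial = e$trial,
                 word_position = e$word_position), r)
  }
  do.call(rbind, out[seq_len(k)])
}

#' Score detected speech events against ground truth
#'
#' @param detected Data frame from [refine_session_events()] (or compatible)
#'   with `participant`, `trial`, `word_position`, `kind`, `time_s`,
#'   `source`.
#' @param truth Ground-truth words table with `true_onset_s`/`true_offset_s`
#'   keyed by `speaker`, `trial`, `word_position`.
#' @return List of metrics: `bias_ms`, `mae_ms`, `median_abs_ms`,
#'   `frac_within_20ms`, `fallback_rate`, `n`.
#' @export
score_events <- function(detected, truth) {
  tr_on <- data.frame(participant = truth$speaker, trial = truth$trial,
                      word_position = truth$word_position, kind = "onset",
                      true_s = truth$true_onset_s)
  tr_off <- data.frame(participant = truth$speaker, trial = truth$trial,
                       word_position = truth$word_position, kind = "offset",
                       true_s = truth$true_offset_s)
  m <- merge(detected, rbind(tr_on, tr_off),
             by = c("participant", "trial", "word_position", "kind"))
  err_ms <- (m$time_s - m$true_s) * 1000
  list(
    bias_ms = mean(err_ms),
    mae_ms = mean(abs(err_ms)),
    median_abs_ms = stats::median(abs(err_ms)),
    frac_within_20ms = mean(abs(err_ms) <= 20),
    fallback_rate = mean(m$source == "coarse_fallback"),
    n = nrow(m),
    errors_ms = err_ms
  )
}
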