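## Amplitude envelope of a synthetic word at arbitrary times (seconds,
## relative to voicing start): raised-cosine attack and decay around a
## sustain with slow sinusoidal amplitude modulation.
.env_at <- function(t, dur, attack, decay, am_phase) {
  e <- numeric(length(t))
  inside <- t >= 0 & t <= dur
  ti <- t[inside]
  v <- rep(1, length(ti))
  atk <- ti < attack
  v[atk] <- 0.5 * (1 - cos(pi * ti[atk] / attack))
  dec <- ti > dur - decay
  v[dec] <- pmin(v[dec], 0.5 * (1 - cos(pi * (dur - ti[dec]) / decay)))
  e[inside] <- pmax(v * (1 + 0.15 * sin(2 * pi * 4 * ti + am_phase)), 0)
  e
}

## Draws everything that defines one synthetic word (duration, voicing,
## amplitude modulation, lip smack) and locates the envelope
## threshold-crossing ground truth. The envelope is evaluated at the audio
## rate only near the attack and decay ramps (crossings can only occur
## there) and on a coarse grid for the sustain peak, so the scheduler can
## call this cheaply for every word; the waveform synthesizer rebuilds the
## identical envelope from the same draws.
.word_profile <- function(n_letters, params, seed, lip_smack = NA) {
  fs <- params$audio_rate
  tm <- params$timing
  with_seed(seed, {
    dur <- exp(log(tm$word_base_s + tm$word_per_letter_s * n_letters) +
                 stats::rnorm(1, 0, tm$word_sdlog))
    if (is.na(lip_smack)) {
      lip_smack <- stats::runif(1) < params$artifacts$lip_smack_prob
    }
    f0 <- stats::runif(1, 110, 180)
    phases <- stats::runif(10, 0, 2 * pi)
    am_phase <- stats::runif(1, 0, 2 * pi)
    lip_lead_s <- stats::runif(1, 0.05, 0.2)

    pad_pre <- 0.30
    pad_post <- 0.20
    n <- round((pad_pre + dur + pad_post) * fs)

    ## envelope peak from a 1 ms grid (the 4 Hz modulation varies slowly)
    peak <- max(.env_at(seq(0, dur, by = 1e-3), dur, tm$attack_s,
                        tm$decay_s, am_phase))
    th <- tm$onset_frac * peak
    ## first/last crossing: sample the ramps at the audio rate
    atk_t <- seq(0, min(tm$attack_s + 0.002, dur), by = 1 / fs)
    above <- which(.env_at(atk_t, dur, tm$attack_s, tm$decay_s,
                           am_phase) >= th)
    onset_rel <- atk_t[min(above)]
    dec_t <- seq(max(0, dur - tm$decay_s - 0.002), dur, by = 1 / fs)
    above2 <- which(.env_at(dec_t, dur, tm$attack_s, tm$decay_s,
                            am_phase) >= th)
    offset_rel <- dec_t[max(above2)]

    list(
      n = n, dur = dur, f0 = f0, phases = phases, am_phase = am_phase,
      lip_smack = lip_smack, lip_lead_s = lip_lead_s, pad_pre = pad_pre,
      onset_s = pad_pre + onset_rel,
      offset_s = pad_pre + offset_rel
    )
  })
}

#' Synthesize the audio of one spoken word
#'
#' Produces a harmonic voiced burst (fundamental drawn from 110-180 Hz with
#' decaying, formant-shaped harmonics) under a smooth amplitude envelope:
#' raised-cosine attack, mildly amplitude-modulated sustain, raised-cosine
#' decay. Word duration follows a lognormal model whose median grows with
#' the letter count (`word_base_s + word_per_letter_s * n_letters`),
#' calibrated to the paradigm's 0.54 +/- 0.07 s grand-average word duration.
#' The true onset and offset are the first and last crossings of
#' `onset_frac` (default 10%) of the envelope peak. With probability
#' `lip_smack_prob` a short broadband click is planted 50-200 ms before the
#' onset, emulating the artifacts the offline onset refinement must reject.
#'
#' @param n_letters Letter count of the word (>= 1).
#' @param params A [synth_params()].
#' @param seed Integer seed; identical `(n_letters, seed)` give identical
#'   waveforms.
#' @param lip_smack Logical override; `NA` (default) draws from
#'   `params$artifacts$lip_smack_prob`.
#' @return List with `wave` (numeric vector at `params$audio_rate`, peak
#'   about 0.3), `onset_s`, `offset_s` (relative to the vector start),
#'   `duration_s` (offset - onset), and `lip_smack` (logical).
#' @export
synth_word_audio <- function(n_letters, params = synth_params(), seed = 1,
                             lip_smack = NA) {
  stopifnot(n_letters >= 1)
  fs <- params$audio_rate
  tm <- params$timing
  prof <- .word_profile(n_letters, params, seed, lip_smack)
  t <- seq_len(prof$n) / fs
  env <- .env_at(t - prof$pad_pre, prof$dur, tm$attack_s, tm$decay_s,
                 prof$am_phase)
  src <- numeric(prof$n)
  voiced <- env > 0
  tv <- t[voiced]
  for (h in 1:10) {
    fh <- h * prof$f0
    if (fh > fs / 2) break
    a <- (1 / h) * (exp(-((fh - 500) / 400)^2) +
                      0.6 * exp(-((fh - 1500) / 700)^2) + 0.1)
    src[voiced] <- src[voiced] + a * sin(2 * pi * fh * tv + prof$phases[h])
  }
  wave <- 0.3 * src * env / max(abs(src * env) + 1e-12)

  if (prof$lip_smack) {
    i0 <- max(1, round((prof$onset_s - prof$lip_lead_s) * fs))
    click_n <- round(0.005 * fs)
    idx <- i0:min(prof$n, i0 + click_n - 1)
    click_env <- sin(pi * seq_along(idx) / length(idx))^2
    click <- with_seed(derive_seed(seed, 99L), stats::rnorm(length(idx)))
    wave[idx] <- wave[idx] + 0.15 * click * click_env
  }

  list(wave = wave, onset_s = prof$onset_s, offset_s = prof$offset_s,
       duration_s = prof$offset_s - prof$onset_s, lip_smack = prof$lip_smack)
}
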