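#' @title Synthetic dyadic session generation
#' @description Internal schedule generator: word-by-word event flow with
#'   gamma reaction times and lognormal word durations, quantized voice-key
#'   markers driving the next presentation.
#' @keywords internal
.session_schedule <- function(plan, params, seed) {
  tm <- params$timing
  rm_ <- params$rt_model
  grid <- params$marker_grid_s
  n_trials <- nrow(plan)

  n_w <- n_trials * 13L
  with_seed(seed, {
    u <- stats::rnorm(2, 0, rm_$participant_sd)
    trial <- rep(seq_len(n_trials), each = 13L)
    pos <- rep(1:13, n_trials)
    starter <- plan$starter[trial]
    speaker <- ifelse(pos %% 2 == 1, starter, 3L - starter)
    listener <- 3L - speaker
    lens <- integer(n_w)
    wordcols <- as.matrix(plan[, paste0("word_", 1:13)])
    lens <- nchar(wordcols[cbind(trial, pos)])
    cong_p <- cbind(plan$congruency_p1, plan$congruency_p2)
    cong_sp <- cong_p[cbind(trial, speaker)]
    cong_li <- cong_p[cbind(trial, listener)]

    eta <- rm_$intercept +
      ifelse(pos >= 8 & cong_sp == "incongruent", rm_$congruency, 0) +
      ifelse(pos == 1, rm_$first_word, 0) +
      rm_$position_slope * (pos - 7) +
      rm_$word_length * (lens - 5) + u[speaker]
    if (any(eta <= 0)) {
      stop("rt model linear predictor is non-positive (inverse-link ",
           "domain violation)", call. = FALSE)
    }
    rt <- stats::rgamma(n_w, shape = rm_$shape, scale = 1 / (eta * rm_$shape))

    word_seed <- derive_seed(seed, trial * 16L + pos)
    dur_true <- numeric(n_w)
    lip <- logical(n_w)
    for (k in seq_len(n_w)) {
      prof <- .word_profile(lens[k], params, word_seed[k])
      dur_true[k] <- prof$offset_s - prof$onset_s
      lip[k] <- prof$lip_smack
    }

    ## sequential timing: each word's visual onset is the previous word's
    ## quantized (voice-key) offset; the first word of a trial follows
    ## fixation + prime after the previous trial's end
    visual_onset <- true_onset <- true_offset <- numeric(n_w)
    coarse_onset <- coarse_offset <- numeric(n_w)
    t_cursor <- params$calibration_s
    for (k in seq_len(n_w)) {
      if (pos[k] == 1L) {
        visual_onset[k] <- t_cursor + tm$fixation_s + tm$prime_s
      } else {
        visual_onset[k] <- coarse_offset[k - 1L]
      }
      true_onset[k] <- visual_onset[k] + rt[k]
      true_offset[k] <- true_onset[k] + dur_true[k]
      coarse_onset[k] <- ceiling(true_onset[k] / grid) * grid
      coarse_offset[k] <- ceiling(true_offset[k] / grid) * grid
      if (pos[k] == 13L) t_cursor <- coarse_offset[k] + tm$iti_s
    }

    sched <- data.frame(
      trial = trial, word_position = pos, speaker = speaker,
      word_length = lens, congruency_speaker = cong_sp,
      congruency_listener = cong_li, visual_onset_s = visual_onset,
      rt_s = rt, true_onset_s = true_onset, true_offset_s = true_offset,
      coarse_onset_s = coarse_onset, coarse_offset_s = coarse_offset,
      word_seed = word_seed, lip_smack = lip, stringsAsFactors = FALSE
    )
    attr(sched, "session_end_s") <- t_cursor
    attr(sched, "participant_intercepts") <- u
    sched
  })
}

#' Generate reaction times for a trial plan
#'
#' Draws per-spoken-word reaction times from the gamma inverse-link model of
#' [synth_params()]: the mean RT is the reciprocal of a linear predictor with
#' fixed congruency (speaker's own label, words 8-13), first-word and
#' word-length effects and random participant intercepts. This is the
#' behavioural half of the simulator; identical seeds give identical tables.
#'
#' @param plan A `trial_plan`.
#' @param params A [synth_params()].
#' @param seed Integer seed.
#' @return Data frame with `participant`, `trial`, `word_position`, `rt`
#'   (seconds), `word_length`, `congruency`, `sequence`
#'   (`cw_even` for CW/CW+2/CW+4, `cw_odd` for CW+1/CW+3/CW+5, else `other`).
#' @export
synth_rts <- function(plan, params = synth_params(), seed = 1) {
  sched <- .session_schedule(plan, params, seed)
  data.frame(
    participant = sched$speaker,
    trial = sched$trial,
    word_position = sched$word_position,
    rt = sched$rt_s,
    word_length = sched$word_length,
    congruency = sched$congruency_speaker,
    sequence = rt_sequence_tag(sched$word_position),
    stringsAsFactors = FALSE
  )
}

#' Simulate reaction times for a whole multi-dyad study
#'
#' Generates one trial plan and RT table per dyad (distinct derived seeds)
#' and stacks them with study-wide participant ids (dyad d contributes
#' participants 2d-1 and 2d), emulating the 13-pair / 26-participant design.
#'
#' @param n_dyads Number of dyads.
#' @param spec A [design_spec()] applied to every dyad.
#' @param params A [synth_params()].
#' @param seed Integer master seed.
#' @return `rt_table` data frame over all dyads, with a `dyad` column.
#' @export
synth_rt_study <- function(n_dyads = 13, spec = design_spec(),
                           params = synth_params(), seed = 1) {
  out <- vector("list", n_dyads)
  sentences <- sentence_lexicon(spec$n_trials)
  for (d in seq_len(n_dyads)) {
    plan <- build_trial_plan(spec, sentences, seed = derive_seed(seed, d))
    tab <- synth_rts(plan, params, seed = derive_seed(seed, 1000L + d))
    tab$participant <- tab$participant + 2L * (d - 1L)
    tab$dyad <- d
    out[[d]] <- tab
  }
  res <- do.call(rbind, out)
  class(res) <- c("rt_table", "data.frame")
  res
}

#' Sequence tag of a word position
#'
#' The critical word is word 8; one participant speaks CW, CW+2, CW+4
#' (positions 8, 10, 12: `cw_even`), the other CW+1, CW+3, CW+5
#' (positions 9, 11, 13: `cw_odd`). Earlier positions are `other`.
#'
#' @param word_position Integer vector of positions 1-13.
#' @return Character vector of tags.
#' @export
rt_sequence_tag <- function(word_position) {
  ifelse(word_position %in% c(8, 10, 12), "cw_even",
         ifelse(word_position %in% c(9, 11, 13), "cw_odd", "other"))
}

## FFT-shaped 1/f^2 background noise, amplitude floored below f_floor
.noise_1f2 <- function(n, rate, sd_target, f_floor = 0.5) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, rate / 2, length.out = nfft / 2 + 1)
  shape <- 1 / pmax(f, f_floor)
  re <- stats::rnorm(nfft / 2 + 1)
  im <- stats::rnorm(nfft / 2 + 1)
  half <- complex(real = re, imaginary = im) * shape
  half[1] <- 0
  half[nfft / 2 + 1] <- complex(real = re[nfft / 2 + 1] * shape[nfft / 2 + 1])
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x * sd_target / stats::sd(x)
}

## Gaussian ERP kernel sampled at the EEG rate; support +/- 4 SD
.erp_kernel <- function(width_ms, rate) {
  half <- ceiling(4 * width_ms / 1000 * rate)
  s <- seq(-half, half)
  list(offsets = s, values = exp(-(s * 1000 / rate)^2 / (2 * width_ms^2)))
}

#' Generate a complete synthetic dyadic session
#'
#' Builds one session with known ground truth: stereo speech audio (one
#' channel per participant), two EEG streams, a coarse voice-key marker
#' stream, and the behavioural/neural truth tables. Word events follow the
#' paradigm timing (0.5 s fixation, 2.5 s prime, each word's visual
#' presentation triggered by the previous word's quantized offset, 1.5 s
#' inter-trial interval). EEG is 1/f^2 background plus alpha, with Gaussian
#' ERP kernels time-locked to the *partner's* true speech onsets; congruency
#' deltas are applied on heard critical words of incongruent listeners, and
#' the first heard word of each trial gets the N100 gain. Blinks and
#' speech-locked jaw EMG are injected after the artifact-free calibration
#' lead-in; coarse markers are true times quantized (ceiling) to the
#' voice-key grid; packet loss is applied when configured.
#'
#' @param plan A `trial_plan`.
#' @param params A [synth_params()].
#' @param seed Integer seed; the session is deterministic in
#'   `(plan, params, seed)`.
#' @return Object of class `session_bundle`: list with `audio` (list of two
#'   numeric channels + `rate`, or `NULL`), `eeg` (list of `eeg_recording`
#'   per participant), `events` (coarse marker stream), `plan`, `truth`
#'   (`words`, `components`, `gaps`), `params`, `session_end_s`.
#' @export
synth_session <- function(plan, params = synth_params(), seed = 1) {
  if (length(params$channels) < 1) stop("configuration error: zero channels")
  if (nrow(plan) < 1) stop("configuration error: empty plan")
  sched <- .session_schedule(plan, params, seed)
  end_s <- attr(sched, "session_end_s")
  fs <- params$audio_rate

  ## ---- audio ----
  audio <- NULL
  if (params$make_audio) {
    n_a <- ceiling(end_s * fs)
    audio <- list(rate = fs, p1 = numeric(n_a), p2 = numeric(n_a))
    for (k in seq_len(nrow(sched))) {
      w <- synth_word_audio(sched$word_length[k], params, sched$word_seed[k])
      i0 <- round((sched$true_onset_s[k] - w$onset_s) * fs)
      idx <- i0 + seq_along(w$wave)
      keep <- idx >= 1 & idx <= n_a
      ch <- if (sched$speaker[k] == 1L) "p1" else "p2"
      audio[[ch]][idx[keep]] <- audio[[ch]][idx[keep]] + w$wave[keep]
    }
  }

  ## ---- marker stream ----
  events <- rbind(
    data.frame(time_s = sched$visual_onset_s, trial = sched$trial,
               word_position = sched$word_position,
               participant = sched$speaker, event_type = "visual",
               congruency = sched$congruency_speaker,
               stringsAsFactors = FALSE),
    data.frame(time_s = sched$coarse_onset_s, trial = sched$trial,
               word_position = sched$word_position,
               participant = sched$speaker,
               event_type = "speech_onset_coarse",
               congruency = sched$congruency_speaker,
               stringsAsFactors = FALSE),
    data.frame(time_s = sched$coarse_offset_s, trial = sched$trial,
               word_position = sched$word_position,
               participant = sched$speaker,
               event_type = "speech_offset_coarse",
               congruency = sched$congruency_speaker,
               stringsAsFactors = FALSE)
  )
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL

  ## ---- EEG ----
  eeg <- list(p1 = NULL, p2 = NULL)
  comp_truth <- list()
  gaps_truth <- list(p1 = NULL, p2 = NULL)
  rate <- params$eeg_rate
  n_e <- ceiling(end_s * rate)
  ch <- params$channels
  nch <- length(ch)
  comp <- params$components

  topo <- lapply(seq_len(nrow(comp)), function(j) {
    topography_weights(comp$center[j], comp$spread[j], ch)
  })
  kern <- lapply(seq_len(nrow(comp)), function(j) {
    .erp_kernel(comp$width_ms[j], rate)
  })
  alpha_topo <- {
    w <- (topography_weights("O1", 0.8, ch) + topography_weights("O2", 0.8, ch))
    w / max(w)
  }
  blink_topo <- {
    w <- (topography_weights("Fp1", 0.6, ch) + topography_weights("Fp2", 0.6, ch))
    pmin(w / max(w) * 1, 1)
  }
  emg_topo <- stats::setNames(numeric(nch), ch)
  for (lbl in intersect(c("T7", "T8"), ch)) emg_topo[lbl] <- 1
  for (lbl in intersect(c("TP9", "TP10"), ch)) emg_topo[lbl] <- 0.7

  for (p in params$eeg_participants) {
    pseed <- derive_seed(seed, 500L + p)
    data <- with_seed(pseed, {
      sd_t <- params$noise$background_sd_uV
      m <- matrix(0, nch, n_e, dimnames = list(ch, NULL))
      if (sd_t > 0) {
        ## spatially correlated floor: a few smooth common sources plus a
        ## smaller channel-specific part, as in real scalp EEG
        n_src <- 8
        W <- vapply(seq_len(n_src), function(k) {
          ctr <- sample(ch, 1)
          sgn <- sample(c(-1, 1), 1)
          sgn * topography_weights(ctr, stats::runif(1, 0.5, 1.0), ch)
        }, numeric(nch))
        shared <- W %*% t(vapply(seq_len(n_src), function(k) {
          .noise_1f2(n_e, rate, 1)
        }, numeric(n_e)))
        shared <- shared * (sd_t * sqrt(0.75)) /
          pmax(apply(shared, 1, stats::sd), 1e-12)
        for (c_i in seq_len(nch)) {
          m[c_i, ] <- shared[c_i, ] +
            .noise_1f2(n_e, rate, sd_t * sqrt(0.25))
        }
      }
      tt <- seq_len(n_e) / rate
      alpha <- params$noise$alpha_amp_uV * sqrt(2) *
        sin(2 * pi * params$noise$alpha_freq * tt + stats::runif(1, 0, 2 * pi)) *
        (0.5 + 0.5 * sin(2 * pi * 0.05 * tt + stats::runif(1, 0, 2 * pi)))
      m + alpha_topo %o% alpha
    })

    ## planted ERPs: locked to the partner's true speech onsets
    heard <- sched[sched$speaker != p, ]
    truth_rows <- vector("list", nrow(heard) * nrow(comp))
    tr_k <- 0L
    ## one latent latency-variability draw per heard event; each component
    ## scales it by its own jitter SD, so jittered components of one event
    ## shift coherently (trial-level processing-speed variability)
    jit_seed <- derive_seed(seed, 600L + p)
    jit_stream <- with_seed(jit_seed, stats::rnorm(nrow(heard)))
    for (e_i in seq_len(nrow(heard))) {
      ev <- heard[e_i, ]
      onset_samp <- round(ev$true_onset_s * rate)
      for (j in seq_len(nrow(comp))) {
        amp <- comp$amplitude_uV[j]
        if (comp$name[j] == "N100" && ev$word_position == 1) {
          amp <- amp * params$first_word_n100_gain
        }
        if (ev$word_position == 8 && ev$congruency_listener == "incongruent") {
          d <- params$congruency_delta_uV[comp$name[j]]
          if (!is.na(d)) amp <- amp + d
        }
        jit_sd <- params$latency_jitter_ms[comp$name[j]]
        jit_ms <- if (!is.na(jit_sd) && jit_sd > 0) {
          jit_stream[e_i] * jit_sd
        } else 0
        lat_ms <- comp$latency_ms[j] + jit_ms
        center <- onset_samp + round(lat_ms / 1000 * rate)
        idx <- center + kern[[j]]$offsets
        keep <- idx >= 1 & idx <= n_e
        if (any(keep)) {
          data[, idx[keep]] <- data[, idx[keep]] +
            (topo[[j]] * amp) %o% kern[[j]]$values[keep]
        }
        tr_k <- tr_k + 1L
        truth_rows[[tr_k]] <- data.frame(
          participant = p, trial = ev$trial,
          word_position = ev$word_position, component = comp$name[j],
          latency_ms = lat_ms, amplitude_uV = amp,
          congruency = ev$congruency_listener, stringsAsFactors = FALSE
        )
      }
    }

    ## artifacts (only after the calibration lead-in)
    art_seed <- derive_seed(seed, 700L + p)
    data <- with_seed(art_seed, {
      n_blinks <- stats::rpois(1, params$artifacts$blink_rate_per_min *
                                 (end_s - params$calibration_s) / 60)
      if (n_blinks > 0 && params$artifacts$blink_amp_uV > 0) {
        at <- stats::runif(n_blinks, params$calibration_s, end_s - 0.3)
        half <- round(0.125 * rate)
        bump <- sin(pi * seq(0, 1, length.out = 2 * half + 1))^2
        for (b in at) {
          i0 <- round(b * rate)
          idx <- i0 + seq(-half, half)
          keep <- idx >= 1 & idx <= n_e
          data[, idx[keep]] <- data[, idx[keep]] +
            (blink_topo * params$artifacts$blink_amp_uV) %o% bump[keep]
        }
      }
      if (params$artifacts$emg_amp_uV > 0) {
        own <- sched[sched$speaker == p, ]
        for (e_i in seq_len(nrow(own))) {
          i0 <- max(1, round(own$true_onset_s[e_i] * rate))
          i1 <- min(n_e, round(own$true_offset_s[e_i] * rate))
          if (i1 > i0) {
            seg <- i0:i1
            noise <- matrix(stats::rnorm(nch * length(seg)), nch)
            data[, seg] <- data[, seg] +
              (emg_topo * params$artifacts$emg_amp_uV) * noise
          }
        }
      }
      data
    })

    rec <- structure(list(
      data = data, labels = ch, rate = rate,
      timestamps = (seq_len(n_e) - 1) / rate, ref = "FCz",
      participant = p
    ), class = "eeg_recording")

    if (!is.null(params$packet_loss)) {
      rec <- inject_packet_loss(rec, params$packet_loss,
                                seed = derive_seed(seed, 800L + p))
      gaps_truth[[paste0("p", p)]] <- attr(rec, "gap_truth")
    }
    eeg[[paste0("p", p)]] <- rec
    comp_truth[[paste0("p", p)]] <- do.call(rbind, truth_rows)
  }

  structure(list(
    audio = audio, eeg = eeg, events = events, plan = plan,
    truth = list(words = sched, components = do.call(rbind, comp_truth),
                 gaps = gaps_truth),
    params = params, session_end_s = end_s
  ), class = "session_bundle")
}

#' Remove samples from an EEG recording to emulate wireless packet loss
#'
#' Samples inside the loss intervals are deleted while timestamps keep real
#' time, so the timestamp delta across a gap exceeds the nominal sample
#' period; markers are untouched (they live on the session clock).
#'
#' @param rec An `eeg_recording`.
#' @param loss Either a fraction in (0, 1) of samples to drop in random
#'   non-overlapping gaps of 20-200 ms, or a list of `c(start_s, duration_s)`
#'   intervals.
#' @param seed Seed for random gap placement.
#' @return The shortened `eeg_recording`, with attribute `"gap_truth"`: a
#'   data frame `start_s`, `duration_s`, `last_index_before` (in the new
#'   indexing), `lost_samples`.
#' @export
inject_packet_loss <- function(rec, loss, seed = 1) {
  n <- ncol(rec$data)
  rate <- rec$rate
  if (is.numeric(loss) && length(loss) == 1 && loss > 0 && loss < 1) {
    target <- loss * n
    iv <- with_seed(seed, {
      out <- list(); got <- 0
      guard <- 0
      while (got < target && guard < 10000) {
        guard <- guard + 1
        d <- stats::runif(1, 0.02, 0.2)
        s <- stats::runif(1, 1, n / rate - d - 1)
        ok <- TRUE
        for (o in out) if (s < o[1] + o[2] + 0.1 && s + d > o[1] - 0.1) {
          ok <- FALSE; break
        }
        if (ok) { out[[length(out) + 1]] <- c(s, d); got <- got + d * rate }
      }
      out
    })
  } else if (is.list(loss)) {
    iv <- loss
  } else {
    stop("loss must be a fraction or a list of (start, duration) intervals")
  }
  if (length(iv) == 0) return(rec)
  iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
  starts <- vapply(iv, `[`, numeric(1), 1)
  durs <- vapply(iv, `[`, numeric(1), 2)
  if (any(starts[-1] < (starts + durs)[-length(iv)])) {
    stop("overlapping loss intervals", call. = FALSE)
  }
  if (any(starts < 0) || any(starts + durs > n / rate)) {
    stop("loss interval outside recording span", call. = FALSE)
  }
  drop <- logical(n)
  truth <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      last_index_before = integer(0), lost_samples = integer(0))
  for (g in seq_along(iv)) {
    idx <- which(rec$timestamps >= starts[g] &
                   rec$timestamps < starts[g] + durs[g])
    if (length(idx) == 0) next
    drop[idx] <- TRUE
    truth <- rbind(truth, data.frame(
      start_s = starts[g], duration_s = durs[g],
      last_index_before = idx[1] - 1L - sum(drop[seq_len(idx[1] - 1L)]),
      lost_samples = length(idx)
    ))
  }
  rec$data <- rec$data[, !drop, drop = FALSE]
  rec$timestamps <- rec$timestamps[!drop]
  attr(rec, "gap_truth") <- truth
  rec
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle> %d trials, %.0f s, audio: %s, EEG streams: %s\n",
    nrow(x$plan), x$session_end_s,
    if (is.null(x$audio)) "none" else "stereo 44.1 kHz",
    paste(names(Filter(Negate(is.null), x$eeg)), collapse = ", ")))
  invisible(x)
}
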