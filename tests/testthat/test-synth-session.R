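test_that("word audio is deterministic with silent pre-onset and sane truth", {
  p <- fx_params()
  w1 <- synth_word_audio(5, p, seed = 3)
  w2 <- synth_word_audio(5, p, seed = 3)
  expect_identical(w1$wave, w2$wave)
  expect_gt(w1$offset_s, w1$onset_s)
  ## silent (exactly zero) before the envelope attack begins
  fs <- p$audio_rate
  pre <- w1$wave[seq_len(round((w1$onset_s - p$timing$attack_s) * fs))]
  expect_true(all(pre == 0))
  ## envelope below the onset threshold right before the true onset
  expect_lt(max(abs(w1$wave[seq_len(round(w1$onset_s * fs) - 1)])),
            0.2 * max(abs(w1$wave)))
})

test_that("word durations grow with letter count and match the duration model", {
  p <- fx_params()
  mean_dur <- function(n_letters, n = 300) {
    mean(vapply(seq_len(n), function(s) {
      wordbyword:::.word_profile(n_letters, p, seed = 20000 + s)$dur
    }, numeric(1)))
  }
  d3 <- mean_dur(3); d5 <- mean_dur(5); d8 <- mean_dur(8)
  expect_lt(d3, d5)
  expect_lt(d5, d8)
  ## configured median model: word_base + per_letter * n, lognormal spread
  expected5 <- (0.30 + 0.045 * 5) * exp(0.12^2 / 2)
  expect_lt(abs(d5 - expected5), 3 * 0.12 * expected5 / sqrt(300))
})

test_that("session markers are quantized, complete and clock-consistent", {
  b <- fx_audio_session()
  n_words <- nrow(b$plan) * 13L
  tw <- b$truth$words
  expect_identical(nrow(tw), n_words)
  ev <- b$events
  expect_identical(sum(ev$event_type == "speech_onset_coarse"), n_words)
  expect_identical(sum(ev$event_type == "speech_offset_coarse"), n_words)
  expect_identical(sum(ev$event_type == "visual"), n_words)
  ## coarse markers: on the 100 ms grid, within (0, 100] ms after truth
  q <- tw$coarse_onset_s / 0.1
  expect_lt(max(abs(q - round(q))), 1e-9)
  expect_true(all(tw$coarse_onset_s - tw$true_onset_s >= 0))
  expect_true(all(tw$coarse_onset_s - tw$true_onset_s < 0.1))
  ## onsets strictly increasing within a trial, alternating speakers
  for (i in unique(tw$trial)) {
    tt <- tw[tw$trial == i, ]
    expect_true(all(diff(tt$true_onset_s) > 0))
    expect_true(all(tt$true_offset_s > tt$true_onset_s))
    expect_true(all(abs(diff(tt$speaker)) == 1))
  }
  ## every marker within the session span
  expect_true(all(ev$time_s >= 0 & ev$time_s <= b$session_end_s))
  ## audio and EEG clocks agree: true onset to EEG sample index error
  ## below half a sample period by construction of the shared clock
  samp <- round(tw$true_onset_s * 500)
  expect_true(all(abs(samp / 500 - tw$true_onset_s) <= 0.5 / 500 + 1e-12))
})

test_that("paradigm timing constants structure the event flow", {
  b <- fx_audio_session()
  tw <- b$truth$words
  first <- tw[tw$trial == 1 & tw$word_position == 1, ]
  ## word 1 appears after fixation (0.5 s) + prime (2.5 s)
  expect_equal(first$visual_onset_s, b$params$calibration_s + 0.5 + 2.5)
  ## each later word is presented at the previous word's coarse offset
  for (i in 1:2) {
    tt <- tw[tw$trial == i, ]
    expect_equal(tt$visual_onset_s[-1], tt$coarse_offset_s[-13])
  }
  ## next trial starts 1.5 s (+ fixation + prime) after the last offset
  t2 <- tw[tw$trial == 2 & tw$word_position == 1, ]
  last1 <- tw[tw$trial == 1 & tw$word_position == 13, ]
  expect_equal(t2$visual_onset_s, last1$coarse_offset_s + 1.5 + 0.5 + 2.5)
})

test_that("synthetic sessions are deterministic in (plan, params, seed)", {
  plan <- fx_plan_small(4)
  p <- fx_params(eeg = 1)
  b1 <- synth_session(plan, p, seed = 9)
  b2 <- synth_session(plan, p, seed = 9)
  expect_identical(b1$audio$p1, b2$audio$p1)
  expect_identical(b1$eeg$p1$data, b2$eeg$p1$data)
  expect_identical(b1$truth$words, b2$truth$words)
})

test_that("null construction: zero deltas leave conditions exchangeable", {
  ## with congruency deltas zeroed the planted heard-CW responses are
  ## identical across conditions; truth amplitudes must agree exactly
  plan <- fx_plan_small(8)
  p <- fx_params(audio = FALSE, eeg = 1,
                 congruency_delta_uV = c(P200 = 0, N400 = 0, P600 = 0))
  b <- synth_session(plan, p, seed = 14)
  tc <- b$truth$components
  cw <- tc[tc$word_position == 8, ]
  agg <- tapply(cw$amplitude_uV, list(cw$component, cw$congruency), mean)
  expect_equal(unname(agg[, "congruent"]), unname(agg[, "incongruent"]))
})

test_that("planted N400 delta is recoverable from the truth-locked average", {
  b <- fx_eeg_session()
  ep <- fx_heard_epochs(b)
  cw <- ep$labels$word_position == 8
  inc <- subset_epochs(ep, cw & ep$labels$congruency == "incongruent")
  cong <- subset_epochs(ep, cw & ep$labels$congruency == "congruent")
  d <- average_epochs(inc) - average_epochs(cong)
  tms <- ep$times
  cpz <- which(ep$channel_labels == "CPz")
  sel <- tms * 1000 > 350 & tms * 1000 <= 500
  trough <- min(d[cpz, sel])
  ## planted -3 microvolt; small session so allow generous Monte-Carlo slack
  expect_lt(trough, -1.2)
  expect_gt(trough, -5)
  ## trough sits inside the kernel window
  t_min <- tms[sel][which.min(d[cpz, sel])]
  expect_gt(t_min, 0.35)
  expect_lte(t_min, 0.5)
})

test_that("reaction times follow the inverse-link gamma model", {
  plan <- build_trial_plan(design_spec(), seed = 2)
  p <- fx_params(audio = FALSE, eeg = integer(0))
  tab <- synth_rts(plan, p, seed = 5)
  expect_identical(nrow(tab), 240L * 13L)
  expect_true(all(tab$rt > 0))
  ## identical seeds give identical tables
  expect_identical(tab, synth_rts(plan, p, seed = 5))
  ## intercept 2.04 on the inverse link: mean RT about 1/2.04 s for
  ## non-initial words (law of large numbers over ~3000 draws)
  mid <- tab$rt[tab$word_position %in% 2:7]
  expect_lt(abs(mean(mid) - 1 / 2.04), 0.02)
  ## first word slower by the planted first-word link shift
  expect_gt(mean(tab$rt[tab$word_position == 1]), mean(mid) + 0.05)
  ## sequence tags
  expect_true(all(tab$sequence[tab$word_position %in% c(8, 10, 12)] == "cw_even"))
  expect_true(all(tab$sequence[tab$word_position %in% c(9, 11, 13)] == "cw_odd"))
  expect_true(all(tab$sequence[tab$word_position < 8] == "other"))
})

test_that("a non-positive linear predictor raises an inverse-link error", {
  plan <- fx_plan_small(4)
  p <- fx_params(audio = FALSE, eeg = integer(0),
                 rt_model = list(intercept = 0.3, congruency = 0,
                                 first_word = -0.5, position_slope = 0,
                                 word_length = 0, participant_sd = 0,
                                 shape = 30))
  expect_error(synth_rts(plan, p, seed = 1), "non-positive")
})

test_that("packet loss removes samples but keeps real-time stamps", {
  rec <- fx_recording(n_s = 20)
  n0 <- ncol(rec$data)
  ## one 100 ms gap at 500 Hz removes exactly 50 samples
  r1 <- inject_packet_loss(rec, list(c(5.0, 0.1)))
  expect_identical(n0 - ncol(r1$data), 50L)
  expect_gt(max(diff(r1$timestamps)), 0.1)
  ## empty loss list: unchanged
  r0 <- inject_packet_loss(rec, list())
  expect_identical(r0$data, rec$data)
  ## overlapping intervals rejected
  expect_error(inject_packet_loss(rec, list(c(1, 0.5), c(1.2, 0.5))),
               "overlap")
  expect_error(inject_packet_loss(rec, list(c(25, 1))), "outside")
})
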