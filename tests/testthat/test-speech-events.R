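test_that("features behave correctly on silence, steps and DC offsets", {
  cfg <- onset_config()
  n <- round(1.5 * 44100)
  ## pure silence: envelope and RMS identically ~0
  f0 <- compute_features(numeric(n), cfg)
  expect_lt(max(f0$envelope), 1e-10)
  expect_lt(max(f0$rms), 1e-10)
  ## 100 Hz tone switched on at the midpoint: envelope rises to a steady
  ## level across the smoother length
  x <- numeric(n)
  half <- seq(round(n / 2), n)
  x[half] <- sin(2 * pi * 200 * half / 44100)
  f1 <- compute_features(x, cfg)
  third <- floor(f1$n / 3)
  expect_lt(max(f1$envelope[seq_len(third)]), 0.05 * max(f1$envelope))
  ## steady-state plateau (clear of the smoother's edge roll-off)
  plateau <- (f1$n - third):(f1$n - 400)
  expect_gt(min(f1$envelope[plateau]), 0.5 * max(f1$envelope))
  expect_gt(min(f1$rms[plateau]), 0.5 * max(f1$rms))
  ## DC-only epoch: erased by the 35 Hz highpass
  f2 <- compute_features(rep(0.5, n), cfg)
  expect_lt(max(f2$envelope) / 0.5, 0.02)
  ## too-short epoch errors
  expect_error(compute_features(numeric(1000), cfg), "shorter")
})

test_that("changepoint detection matches exhaustive search on short traces", {
  ## single change: the detected split equals the argmin of the two-segment
  ## cost over all split points
  exhaustive_one <- function(x, min_seg = 15) {
    n <- length(x)
    best <- Inf; at <- NA
    for (k in min_seg:(n - min_seg)) {
      c1 <- sum((x[1:k] - mean(x[1:k]))^2)
      c2 <- sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
      if (c1 + c2 < best) { best <- c1 + c2; at <- k }
    }
    list(cost = best, at = at)
  }
  for (seed in 1:20) {
    x <- wordbyword:::with_seed(seed, {
      m <- sample(40:160, 1)
      c(rnorm(m, 0, 0.05), rnorm(200 - m, 1, 0.05))
    })
    cp <- detect_rms_changepoints(x, penalty = 2)
    ex <- exhaustive_one(x)
    expect_length(cp, 1)
    expect_lte(abs(cp - ex$at), 1)
  }
  ## two changes recovered against a brute-force two-changepoint oracle
  exhaustive_two <- function(x, min_seg = 15) {
    n <- length(x); best <- Inf; at <- c(NA, NA)
    for (k1 in min_seg:(n - 2 * min_seg)) {
      for (k2 in (k1 + min_seg):(n - min_seg)) {
        cst <- sum((x[1:k1] - mean(x[1:k1]))^2) +
          sum((x[(k1 + 1):k2] - mean(x[(k1 + 1):k2]))^2) +
          sum((x[(k2 + 1):n] - mean(x[(k2 + 1):n]))^2)
        if (cst < best) { best <- cst; at <- c(k1, k2) }
      }
    }
    at
  }
  x2 <- wordbyword:::with_seed(1, {
    c(rnorm(70, 0, 0.05), rnorm(60, 1, 0.05), rnorm(70, 0.3, 0.05))
  })
  cp2 <- detect_rms_changepoints(x2, penalty = 1)
  ex2 <- exhaustive_two(x2)
  expect_length(cp2, 2)
  expect_true(all(abs(cp2 - ex2) <= 1))
  ## constant trace: no candidates
  expect_length(detect_rms_changepoints(rep(2, 300)), 0)
})

test_that("validation rejects clicks and accepts sustained voicing", {
  cfg <- onset_config()
  ## empty candidate list -> NULL
  f <- compute_features(numeric(round(1.5 * 44100)), cfg)
  expect_null(validate_candidates(integer(0), f, cfg))
  ## word with a planted lip smack: the click precedes true voicing but the
  ## refined onset must stay at the voicing onset
  p <- fx_params(lip_smack = 1)
  errs <- vapply(1:10, function(s) {
    w <- synth_word_audio(5, p, seed = s, lip_smack = TRUE)
    aud <- numeric(3 * 44100)
    aud[round(1.0 * 44100) + seq_along(w$wave)] <- w$wave
    t_on <- 1.0 + w$onset_s
    r <- refine_onset(aud, ceiling(t_on / 0.1) * 0.1, cfg)
    expect_identical(r$source, "refined")
    (r$time_s - t_on) * 1000
  }, numeric(1))
  ## no early capture by the click (which sits 50-200 ms before the onset)
  expect_true(all(errs > -30))
  expect_lt(median(abs(errs)), 5)
})

test_that("onset refinement reaches millisecond accuracy on clean sessions", {
  b <- fx_audio_session()
  ev <- refine_session_events(b)
  on <- score_events(ev[ev$kind == "onset", ], b$truth$words)
  off <- score_events(ev[ev$kind == "offset", ], b$truth$words)
  expect_lte(on$median_abs_ms, 5)
  expect_lte(abs(on$bias_ms), 2)
  expect_identical(on$fallback_rate, 0)
  expect_lte(off$median_abs_ms, 5)
  ## refined onsets are strictly finer than the 100 ms voice-key grid
  tt <- ev$time_s[ev$source == "refined"] / 0.1
  expect_gt(mean(abs(tt - round(tt)) > 1e-6), 0.95)
  ## monotonicity: within a trial refined onsets are strictly increasing
  ons <- ev[ev$kind == "onset", ]
  for (i in unique(ons$trial)) {
    tt <- ons[ons$trial == i, ]
    tt <- tt[order(tt$word_position), ]
    expect_true(all(diff(tt$time_s) > 0))
  }
  ## offsets follow their onsets
  m <- merge(ev[ev$kind == "onset", ], ev[ev$kind == "offset", ],
             by = c("participant", "trial", "word_position"))
  expect_true(all(m$time_s.y > m$time_s.x))
})

test_that("refinement is deterministic and falls back on silence", {
  b <- fx_audio_session()
  w1 <- b$truth$words[1, ]
  aud <- b$audio[[paste0("p", w1$speaker)]]
  r1 <- refine_onset(aud, w1$coarse_onset_s)
  r2 <- refine_onset(aud, w1$coarse_onset_s)
  expect_identical(r1, r2)
  ## silent stretch: coarse fallback
  silent <- numeric(3 * 44100)
  r3 <- refine_onset(silent, 1.5)
  expect_identical(r3$source, "coarse_fallback")
  expect_identical(r3$time_s, 1.5)
  r4 <- refine_offset(silent, 1.5)
  expect_identical(r4$source, "coarse_fallback")
  ## marker outside the audio errors
  expect_error(refine_onset(silent, 10), "outside")
})

test_that("offset refinement is the time-reversed onset procedure", {
  ## reversing the audio maps offsets onto onsets: refining the offset of a
  ## word equals 'total duration minus refined onset of the reversed signal'
  p <- fx_params()
  w <- synth_word_audio(5, p, seed = 8, lip_smack = FALSE)
  n <- 3 * 44100
  aud <- numeric(n)
  aud[round(1.0 * 44100) + seq_along(w$wave)] <- w$wave
  t_off <- 1.0 + w$offset_s
  coarse_off <- ceiling(t_off / 0.1) * 0.1
  r_off <- refine_offset(aud, coarse_off)
  rev_aud <- rev(aud)
  t_rev <- n / 44100 - coarse_off
  ## a reversed-time onset marker that quantizes like the voice-key
  r_on_rev <- refine_onset(rev_aud, t_rev + (coarse_off - t_off))
  expect_equal(r_off$time_s, n / 44100 - r_on_rev$time_s, tolerance = 2e-3)
})

test_that("score_events matches brute-force recomputation", {
  b <- fx_audio_session()
  tw <- b$truth$words
  det <- data.frame(participant = tw$speaker, trial = tw$trial,
                    word_position = tw$word_position, kind = "onset",
                    time_s = tw$true_onset_s, source = "refined")
  s0 <- score_events(det, tw)
  expect_equal(s0$bias_ms, 0)
  expect_equal(s0$mae_ms, 0)
  expect_identical(s0$frac_within_20ms, 1)
  ## constant +10 ms shift
  det$time_s <- det$time_s + 0.010
  s1 <- score_events(det, tw)
  expect_equal(s1$bias_ms, 10, tolerance = 1e-9)
  expect_equal(s1$mae_ms, 10, tolerance = 1e-9)
  ## randomized detections vs brute force
  set.seed(4)
  det$time_s <- tw$true_onset_s + rnorm(nrow(tw), 0, 0.02)
  det$source <- sample(c("refined", "coarse_fallback"), nrow(tw), TRUE)
  s2 <- score_events(det, tw)
  err <- (det$time_s - tw$true_onset_s) * 1000
  expect_equal(s2$bias_ms, mean(err))
  expect_equal(s2$mae_ms, mean(abs(err)))
  expect_equal(s2$frac_within_20ms, mean(abs(err) <= 20))
  expect_equal(s2$fallback_rate, mean(det$source == "coarse_fallback"))
})
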