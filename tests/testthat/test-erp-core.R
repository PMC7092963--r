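make_rec <- function(data, rate = 500) {
  if (is.null(rownames(data))) rownames(data) <- wbw_montage[seq_len(nrow(data))]
  structure(list(data = data, labels = rownames(data), rate = rate,
                 timestamps = (seq_len(ncol(data)) - 1) / rate, ref = "FCz"),
            class = "eeg_recording")
}

test_that("the band-pass filter has the required frequency response", {
  rate <- 500
  t <- (0:(30 * rate - 1)) / rate
  mid <- seq(10 * rate, 20 * rate)
  ## 10 Hz passband tone: amplitude within 5%, phase shift ~ 0
  x <- matrix(sin(2 * pi * 10 * t), 1)
  y <- bandpass(x, 0.1, 30)
  expect_lt(abs(max(abs(y[1, mid])) - 1), 0.05)
  expect_gt(cor(y[1, mid], x[1, mid]), 0.999)  # zero-phase
  ## 50 Hz: attenuated by at least 20 dB
  x50 <- matrix(sin(2 * pi * 50 * t), 1)
  y50 <- bandpass(x50, 0.1, 30)
  expect_lt(max(abs(y50[1, mid])), 0.1)
  ## DC removed to <= 1%
  xdc <- matrix(rep(1, length(t)), 1)
  ydc <- bandpass(xdc, 0.1, 30)
  expect_lt(max(abs(ydc[1, mid])), 0.01)
  ## invalid band errors
  expect_error(bandpass(x, 30, 10), "invalid band")
})

test_that("bad-channel detection flags flat and decorrelated channels", {
  rec <- fx_recording(n_s = 70)
  expect_identical(detect_bad_channels(rec), character(0))
  rec2 <- rec
  rec2$data[3, ] <- 0.123           # constant
  rec2$data[10, ] <- 40 * wordbyword:::with_seed(1, rnorm(ncol(rec2$data)))
  bad <- detect_bad_channels(rec2)
  expect_setequal(bad, rec$labels[c(3, 10)])
  ## deterministic
  expect_identical(bad, detect_bad_channels(rec2))
  expect_error(detect_bad_channels(fx_recording(n_s = 10)), "60 s")
})

test_that("burst cleaning is identity on calm data and removes blinks", {
  rec <- fx_recording(n_s = 60)
  out <- clean_bursts(rec, c(0, 20), cutoff_k = 8)
  expect_lt(max(abs(out$data - rec$data)), 1e-9)
  ## enormous cutoff: identity even with artifacts present
  rec_blink <- rec
  bump <- sin(pi * seq(0, 1, length.out = 126))^2
  topo <- pmin(topography_weights("Fp1", 0.6) + topography_weights("Fp2", 0.6), 1)
  idx <- 15000 + seq_along(bump)
  rec_blink$data[, idx] <- rec_blink$data[, idx] + (topo * 500) %o% bump
  out_inf <- clean_bursts(rec_blink, c(0, 20), cutoff_k = 1e9)
  expect_lt(max(abs(out_inf$data - rec_blink$data)), 1e-9)
  ## planted 500 uV blink: frontal variance drops >= 80%, central signal kept
  out_b <- clean_bursts(rec_blink, c(0, 20), cutoff_k = 8)
  fp1 <- which(rec$labels == "Fp1")
  cpz <- which(rec$labels == "CPz")
  v_pre <- stats::var(rec_blink$data[fp1, idx])
  v_post <- stats::var(out_b$data[fp1, idx] - rec$data[fp1, idx] * 0)
  expect_lt(stats::var(out_b$data[fp1, idx]) / v_pre, 0.2)
  ## untouched stretch identical
  calm <- 25000:29000
  expect_lt(max(abs(out_b$data[cpz, calm] - rec_blink$data[cpz, calm])), 1e-9)
  expect_error(clean_bursts(rec, c(0, 0.1), cutoff_k = 8), "calibration")
})

test_that("re-referencing to mastoids has its algebraic identities", {
  rec <- fx_recording(n_s = 60)
  rr <- rereference(rec)
  i9 <- match(c("TP9", "TP10"), rec$labels)
  expect_lt(max(abs(colMeans(rr$data[i9, ]))), 1e-9)
  ## idempotent once the reference pair is zero-mean
  rr2 <- rereference(rr)
  expect_lt(max(abs(rr2$data - rr$data)), 1e-9)
  ## all-channels-equal input maps to zero
  same <- make_rec(matrix(rep(sin(1:1000 / 10), each = 24), 24))
  expect_lt(max(abs(rereference(same)$data)), 1e-12)
  expect_error(rereference(make_rec(matrix(0, 4, 100))), "not present")
})

test_that("spherical-spline interpolation reconstructs smooth topographies", {
  rec <- fx_recording(n_s = 10)
  ## constants are reproduced exactly
  const <- make_rec(matrix(2.5, 24, 200))
  ic <- interpolate_channels(const, "CP1")
  expect_lt(max(abs(ic$data[match("CP1", ic$labels), ] - 2.5)), 1e-6)
  ## empty set: identity
  expect_identical(interpolate_channels(rec, character(0))$data, rec$data)
  ## leave-one-out on spatially smooth data: r >= 0.95
  smooth <- wordbyword:::with_seed(6, {
    W <- vapply(1:8, function(k) {
      topography_weights(sample(wbw_montage, 1), runif(1, 0.5, 1))
    }, numeric(24))
    W %*% matrix(rnorm(8 * 2000), 8)
  })
  rownames(smooth) <- wbw_montage
  sm <- make_rec(smooth)
  truth <- sm$data[match("CP1", sm$labels), ]
  sm$data[match("CP1", sm$labels), ] <- 0
  ip <- interpolate_channels(sm, "CP1")
  expect_gte(cor(ip$data[match("CP1", sm$labels), ], truth), 0.95)
  expect_error(interpolate_channels(make_rec(matrix(0, 5, 10)),
                                    c("Fp1", "Fp2")),
               "good channels")
})

test_that("epoching applies the half-open windows and baseline exactly", {
  rec <- fx_recording(n_s = 30)
  events <- data.frame(sample = c(100, 3000, 7000, ncol(rec$data) - 10),
                       event_type = "heard")
  ep <- epoch_recording(rec, events)
  ## boundary events dropped with a reason
  expect_identical(dim(ep$epochs)[1], 2L)
  expect_identical(nrow(ep$dropped), 2L)
  expect_true(all(ep$dropped$reason == "outside recording"))
  ## window (-500, 1500] ms at 500 Hz: 1000 samples, -249..750
  expect_identical(dim(ep$epochs)[3], 1000L)
  expect_equal(ep$times[1], -249 / 500)
  expect_equal(ep$times[1000], 1.5)
  ## baseline mean exactly zero per channel per epoch
  bsel <- which(ep$times > -0.1 & ep$times <= 0)
  expect_identical(length(bsel), 50L)
  for (j in 1:2) {
    expect_lt(max(abs(rowMeans(ep$epochs[j, , bsel]))), 1e-10)
  }
  ## epoch values equal the raw data minus that baseline (brute force)
  j <- 1
  raw <- rec$data[, events$sample[2] + (-249:750)]
  raw <- raw - rowMeans(rec$data[, events$sample[2] + (-49:0)])
  expect_equal(ep$epochs[1, , ], unname(raw), tolerance = 1e-12)
  ## epochs overlapping packet-loss gaps are dropped
  rl <- inject_packet_loss(rec, list(c(6.0, 0.1)))
  ep2 <- epoch_recording(rl, data.frame(sample = c(3000, 9000), event_type = "x"))
  expect_identical(dim(ep2$epochs)[1], 1L)
  expect_true(any(grepl("gap", ep2$dropped$reason)))
})

test_that("3-SD rejection matches its brute-force definition", {
  b <- fx_eeg_session()
  ep <- fx_heard_epochs(b)
  n <- dim(ep$epochs)[1]
  s <- vapply(seq_len(n), function(j) max(abs(ep$epochs[j, , ])), numeric(1))
  thr <- mean(s) + 3 * sd(s)
  kept <- reject_3sd(ep)
  expect_identical(kept$rejected$index, which(s > thr))
  ## identical epochs: zero SD pool rejects none
  same <- ep
  for (j in seq_len(n)) same$epochs[j, , ] <- ep$epochs[1, , ]
  expect_identical(nrow(reject_3sd(same)$rejected), 0L)
  ## a single 100x-scaled epoch among clean ones is exactly the one removed
  out <- ep
  out$epochs[4, , ] <- out$epochs[4, , ] * 100
  rej <- reject_3sd(out)
  expect_identical(rej$rejected$index, 4L)
  expect_error(reject_3sd(subset_epochs(ep, 1:3)), "at least 5")
})

test_that("count matching subsamples the larger condition reproducibly", {
  b <- fx_eeg_session()
  ep <- fx_heard_epochs(b)
  cw <- ep$labels$word_position == 8
  a <- subset_epochs(ep, cw & ep$labels$congruency == "congruent")
  bb <- subset_epochs(ep, cw & ep$labels$congruency == "incongruent")
  m <- match_counts(a, bb, seed = 2)
  expect_identical(dim(m$a$epochs)[1], dim(m$b$epochs)[1])
  expect_identical(dim(m$b$epochs)[1],
                   min(dim(a$epochs)[1], dim(bb$epochs)[1]))
  m2 <- match_counts(a, bb, seed = 2)
  expect_identical(m$a$epochs, m2$a$epochs)
  ## equal counts: identity
  eq <- match_counts(bb, bb, seed = 5)
  expect_identical(eq$a$epochs, bb$epochs)
  ## order preserved
  expect_true(!is.unsorted(match(m$a$labels$trial, a$labels$trial)))
})
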