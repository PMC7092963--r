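#' Zero-phase FIR bandpass filter for EEG recordings
#'
#' Hann-windowed sinc FIR with -6 dB amplitude at the cutoff frequencies,
#' applied as a forward pass of the linear-phase kernel with group-delay
#' compensation (zero net phase). The default 0.1-30 Hz band is the
#' standard ERP band for this paradigm.
#'
#' @param rec An `eeg_recording` (or a channels x samples matrix).
#' @param low,high Cutoffs in Hz (-6 dB points).
#' @param taps Kernel length (odd); the default gives a transition narrow
#'   enough for a 0.1 Hz highpass edge at 500 Hz.
#' @return The filtered recording (same class as input).
#' @export
bandpass <- function(rec, low = 0.1, high = 30, taps = 16501) {
  mat <- if (inherits(rec, "eeg_recording")) rec$data else rec
  rate <- if (inherits(rec, "eeg_recording")) rec$rate else 500
  if (low <= 0 || high <= low || high >= rate / 2) {
    stop("invalid band: need 0 < low < high < rate/2", call. = FALSE)
  }
  if (taps %% 2 == 0) taps <- taps + 1
  ## bandpass = lowpass(high) - lowpass(low); Hann-windowed sinc kernels
  h <- .fir_lowpass_kernel(taps, high, rate) -
    .fir_lowpass_kernel(taps, low, rate)
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- .fir_apply(mat[i, ], h)
  if (inherits(rec, "eeg_recording")) {
    rec$data <- out
    rec
  } else {
    out
  }
}

#' Flag flat or decorrelated EEG channels
#'
#' A channel is bad when its signal is essentially flat (SD below
#' `flat_sd_uV`) or when its best absolute correlation with any other
#' channel stays below `corr_threshold` (independent high-amplitude noise
#' decorrelates from all neighbours; genuine EEG does not). Deterministic.
#'
#' @param rec An `eeg_recording` with at least 60 s of data.
#' @param flat_sd_uV Flatness threshold (microvolt).
#' @param corr_threshold Minimum acceptable best-neighbour |correlation|.
#' @return Character vector of bad channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, flat_sd_uV = 1e-3,
                                corr_threshold = 0.25) {
  if (ncol(rec$data) < 60 * rec$rate) {
    stop("need at least 60 s of data", call. = FALSE)
  }
  ## subsample columns for the correlation estimate (deterministic grid)
  idx <- seq(1, ncol(rec$data), by = max(1, floor(ncol(rec$data) / 5e4)))
  x <- t(rec$data[, idx, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  flat <- sds < flat_sd_uV
  bad <- rec$labels[flat]
  ok <- !flat
  if (sum(ok) >= 2) {
    cc <- abs(stats::cor(x[, ok, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    best <- apply(cc, 2, max)
    bad <- c(bad, rec$labels[ok][best < corr_threshold])
  }
  unique(bad)
}

#' Burst artifact cleaning by calibrated subspace reconstruction
#'
#' Simplified sliding-window burst cleaner in the spirit of artifact
#' subspace reconstruction: principal directions are learned from an
#' artifact-light calibration segment; in each half-overlapping window,
#' components whose RMS exceeds `cutoff_k` times their calibration RMS are
#' treated as artifact directions, projected out, and the window is remixed
#' and cross-faded back. Windows with no deviant component are left
#' untouched.
#'
#' @param rec An `eeg_recording`.
#' @param calibration Either `c(start_s, end_s)` into the recording or a
#'   channels x samples matrix of clean data.
#' @param cutoff_k Deviance cutoff in multiples of calibration component RMS.
#' @param window_s Sliding window length (s).
#' @return Cleaned `eeg_recording`; attribute `"n_windows_cleaned"` reports
#'   how many windows were reconstructed.
#' @export
clean_bursts <- function(rec, calibration, cutoff_k = 8, window_s = 0.5) {
  if (is.matrix(calibration)) {
    calib <- calibration
  } else {
    i0 <- max(1, round(calibration[1] * rec$rate) + 1)
    i1 <- min(ncol(rec$data), round(calibration[2] * rec$rate))
    calib <- rec$data[, i0:i1, drop = FALSE]
  }
  w <- round(window_s * rec$rate)
  if (ncol(calib) < w) stop("calibration shorter than window", call. = FALSE)
  mu <- rowMeans(calib)
  cc <- calib - mu
  C <- tcrossprod(cc) / (ncol(cc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  ref_rms <- sqrt(pmax(eg$values, 1e-12))

  n <- ncol(rec$data)
  x <- rec$data - mu
  hop <- floor(w / 2)
  starts <- seq(1, max(1, n - w + 1), by = hop)
  cleaned <- 0L
  taper_n <- max(2, floor(w * 0.1))
  taper <- c(0.5 * (1 - cos(pi * seq_len(taper_n) / (taper_n + 1))),
             rep(1, w - 2 * taper_n),
             rev(0.5 * (1 - cos(pi * seq_len(taper_n) / (taper_n + 1)))))
  for (s in starts) {
    e <- min(n, s + w - 1)
    seg <- x[, s:e, drop = FALSE]
    y <- crossprod(V, seg)
    rms <- sqrt(rowMeans(y^2))
    dev <- rms > cutoff_k * ref_rms
    if (!any(dev)) next
    cleaned <- cleaned + 1L
    y[dev, ] <- 0
    rebuilt <- V %*% y
    tp <- taper[seq_len(e - s + 1)]
    x[, s:e] <- seg * rep(1 - tp, each = nrow(x)) +
      rebuilt * rep(tp, each = nrow(x))
  }
  rec$data <- x + mu
  attr(rec, "n_windows_cleaned") <- cleaned
  rec
}

#' Re-reference an EEG recording to averaged mastoids
#'
#' Subtracts the mean of the two reference channels (default TP9/TP10) from
#' every channel.
#'
#' @param rec An `eeg_recording`.
#' @param refs Reference channel labels.
#' @return Re-referenced recording (`rec$ref` updated).
#' @export
rereference <- function(rec, refs = c("TP9", "TP10")) {
  miss <- setdiff(refs, rec$labels)
  if (length(miss)) {
    stop("reference channel(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  refsig <- colMeans(rec$data[match(refs, rec$labels), , drop = FALSE])
  rec$data <- rec$data - rep(refsig, each = nrow(rec$data))
  rec$ref <- paste(refs, collapse = "/")
  rec
}

## Perrin-style spherical-spline g function (order m = 4)
.spline_g <- function(cosang, m = 4, n_terms = 20) {
  out <- matrix(0, nrow(cosang), ncol(cosang))
  ## iterative Legendre polynomials
  p_nm1 <- matrix(1, nrow(cosang), ncol(cosang))
  p_n <- cosang
  for (deg in 1:n_terms) {
    if (deg > 1) {
      p_new <- ((2 * deg - 1) * cosang * p_n - (deg - 1) * p_nm1) / deg
      p_nm1 <- p_n
      p_n <- p_new
    }
    out <- out + (2 * deg + 1) / (deg^m * (deg + 1)^m) * p_n
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of missing channels
#'
#' Reconstructs the listed channels from the remaining good channels with
#' order-4 spherical splines on the unit-sphere electrode positions
#' (regularization `lambda` on the spline coefficients). Interpolating an
#' empty set is the identity.
#'
#' @param rec An `eeg_recording`.
#' @param missing Labels of channels to reconstruct.
#' @param positions Electrode positions as from [montage_positions()].
#' @param lambda Ridge regularization (default 1e-5).
#' @return Recording with the missing channels replaced by interpolated
#'   signals.
#' @export
interpolate_channels <- function(rec, missing,
                                 positions = montage_positions(rec$labels),
                                 lambda = 1e-5) {
  if (length(missing) == 0) return(rec)
  miss_idx <- match(missing, rec$labels)
  if (anyNA(miss_idx)) stop("unknown channel in `missing`", call. = FALSE)
  good_idx <- setdiff(seq_along(rec$labels), miss_idx)
  if (length(good_idx) < 4) stop("need >= 4 good channels", call. = FALSE)
  pg <- positions[good_idx, , drop = FALSE]
  pm <- positions[miss_idx, , drop = FALSE]
  G <- .spline_g(tcrossprod(pg))           # good x good
  Gm <- .spline_g(tcrossprod(pm, pg))      # missing x good
  ng <- nrow(pg)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good_idx, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  c_coef <- sol[seq_len(ng), , drop = FALSE]
  d_coef <- sol[ng + 1, ]
  rec$data[miss_idx, ] <- Gm %*% c_coef +
    rep(d_coef, each = length(miss_idx))
  rec
}

#' Epoch an EEG recording around events
#'
#' Cuts half-open `(window[1], window[2]]` epochs (default -500 to 1500 ms)
#' around event samples and subtracts the per-channel mean of the baseline
#' window (default -100 to 0 ms). Events whose epoch would cross the
#' recording edge or overlap a detected packet-loss gap are dropped with a
#' reason.
#'
#' @param rec An `eeg_recording`.
#' @param events Data frame with column `sample` (1-based event sample) and
#'   any label columns (`event_type`, `congruency`, `word_position`, ...).
#' @param window Epoch window in seconds, half-open `(start, end]`.
#' @param baseline Baseline window in seconds, half-open; `NULL` disables
#'   baseline correction.
#' @param gaps Optional [detect_gaps()] result; computed from the
#'   recording's timestamps when `NULL`.
#' @return Object of class `epoch_set`: list with `epochs` (trials x
#'   channels x samples array), `times` (s), `labels` (the retained event
#'   rows), `rate`, `channel_labels`, `dropped` (data frame with reasons).
#' @export
epoch_recording <- function(rec, events, window = c(-0.5, 1.5),
                            baseline = c(-0.1, 0), gaps = NULL) {
  rate <- rec$rate
  offs <- window_to_offsets(window, rate)
  n <- ncol(rec$data)
  if (is.null(gaps)) gaps <- detect_gaps(rec$timestamps, rate)
  keep <- logical(nrow(events))
  reason <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- events$sample[i]
    lo <- s + offs[1]
    hi <- s + offs[length(offs)]
    if (lo < 1 || hi > n) {
      reason[i] <- "outside recording"
      next
    }
    if (nrow(gaps) && any(gaps$last_index_before >= lo &
                            gaps$last_index_before < hi)) {
      reason[i] <- "overlaps packet-loss gap"
      next
    }
    keep[i] <- TRUE
  }
  kept <- which(keep)
  arr <- array(0, dim = c(length(kept), nrow(rec$data), length(offs)))
  for (j in seq_along(kept)) {
    arr[j, , ] <- rec$data[, events$sample[kept[j]] + offs, drop = FALSE]
  }
  times <- offs / rate
  if (!is.null(baseline)) {
    bidx <- which(times > baseline[1] & times <= baseline[2])
    if (length(bidx)) {
      for (j in seq_len(dim(arr)[1])) {
        bm <- rowMeans(arr[j, , bidx])      # per-channel baseline mean
        arr[j, , ] <- arr[j, , ] - bm
      }
    }
  }
  structure(list(
    epochs = arr, times = times,
    labels = events[kept, , drop = FALSE],
    rate = rate, channel_labels = rec$labels,
    dropped = data.frame(event = which(!keep), reason = reason[!keep])
  ), class = "epoch_set")
}

#' Reject epochs exceeding three standard deviations of the deviance pool
#'
#' The per-epoch deviance statistic is the peak absolute amplitude across
#' channels and samples; epochs whose statistic exceeds `mean + 3 SD` of the
#' pool are removed. Applied once (no iteration); with zero pool SD nothing
#' is rejected. Alternative statistic `"gfp"` uses the epoch mean global
#' field power.
#'
#' @param ep An `epoch_set` (>= 5 epochs).
#' @param n_sd Rejection threshold in SDs (default 3).
#' @param stat `"peak"` (default) or `"gfp"`.
#' @return The pruned `epoch_set`; rejected indices and reasons appended to
#'   `$dropped` and recorded in `$rejected`.
#' @export
reject_3sd <- function(ep, n_sd = 3, stat = c("peak", "gfp")) {
  stat <- match.arg(stat)
  n_ep <- dim(ep$epochs)[1]
  if (n_ep < 5) stop("need at least 5 epochs", call. = FALSE)
  s <- vapply(seq_len(n_ep), function(j) {
    if (stat == "peak") {
      max(abs(ep$epochs[j, , ]))
    } else {
      mean(apply(ep$epochs[j, , , drop = FALSE], 3, stats::sd))
    }
  }, numeric(1))
  thr <- mean(s) + n_sd * stats::sd(s)
  bad <- if (stats::sd(s) == 0) integer(0) else which(s > thr)
  ep$rejected <- data.frame(index = bad, statistic = s[bad],
                            threshold = rep(thr, length(bad)))
  if (length(bad)) {
    ep$epochs <- ep$epochs[-bad, , , drop = FALSE]
    ep$labels <- ep$labels[-bad, , drop = FALSE]
  }
  ep
}

#' Subsample the larger of two epoch sets to matched trial counts
#'
#' Conditions are compared with equal trial numbers; the larger set is
#' randomly subsampled (seeded, without replacement, order preserved) to the
#' size of the smaller one.
#'
#' @param ep_a,ep_b `epoch_set`s of the two conditions.
#' @param seed Integer seed.
#' @return List with elements `a` and `b`.
#' @export
match_counts <- function(ep_a, ep_b, seed = 1) {
  na <- dim(ep_a$epochs)[1]
  nb <- dim(ep_b$epochs)[1]
  if (na == 0 || nb == 0) stop("empty epoch set", call. = FALSE)
  take <- function(ep, k) {
    n <- dim(ep$epochs)[1]
    if (n == k) return(ep)
    sel <- sort(with_seed(seed, sample.int(n, k)))
    ep$epochs <- ep$epochs[sel, , , drop = FALSE]
    ep$labels <- ep$labels[sel, , drop = FALSE]
    ep
  }
  k <- min(na, nb)
  list(a = take(ep_a, k), b = take(ep_b, k))
}

#' Combine epoch sets (e.g. the two participants of a dyad)
#'
#' Concatenates epochs along the trial dimension; channel layout, time axis
#' and rate must agree.
#'
#' @param ... `epoch_set`s (or a single list of them).
#' @return One `epoch_set`.
#' @export
combine_epochs <- function(...) {
  eps <- list(...)
  if (length(eps) == 1 && !inherits(eps[[1]], "epoch_set")) eps <- eps[[1]]
  stopifnot(length(eps) >= 1)
  base <- eps[[1]]
  for (e in eps[-1]) {
    stopifnot(identical(e$channel_labels, base$channel_labels),
              isTRUE(all.equal(e$times, base$times)))
    both <- array(0, dim = c(dim(base$epochs)[1] + dim(e$epochs)[1],
                             dim(base$epochs)[2], dim(base$epochs)[3]))
    if (dim(base$epochs)[1]) both[seq_len(dim(base$epochs)[1]), , ] <- base$epochs
    if (dim(e$epochs)[1]) {
      both[dim(base$epochs)[1] + seq_len(dim(e$epochs)[1]), , ] <- e$epochs
    }
    base$epochs <- both
    common <- intersect(names(base$labels), names(e$labels))
    base$labels <- rbind(base$labels[, common, drop = FALSE],
                         e$labels[, common, drop = FALSE])
  }
  base
}

#' Average an epoch set into an ERP matrix
#'
#' @param ep An `epoch_set`.
#' @return Channels x samples matrix with channel rownames; attribute
#'   `"times"`.
#' @export
average_epochs <- function(ep) {
  m <- apply(ep$epochs, c(2, 3), mean)
  rownames(m) <- ep$channel_labels
  attr(m, "times") <- ep$times
  m
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g..%g s)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              min(x$times), max(x$times)))
  invisible(x)
}
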