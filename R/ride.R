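#' Configuration for latency-corrected ERP decomposition
#'
#' Defines the component clusters of the iterative single-trial
#' decomposition: a stimulus-locked component S (0-250 ms, covering the
#' N100), and two cognitive components with free single-trial latencies,
#' C1 (150-350 ms, the P200) and C2 (300-700 ms, the N400). No response
#' cluster is used because the paradigm requires no overt manual response.
#'
#' @param components Data frame: `name`, `start_ms`, `end_ms`, `locked`.
#' @param max_iterations Iteration cap of the alternating estimation.
#' @param tol_uV Convergence tolerance: RMS change of the component
#'   waveforms between iterations.
#' @param xc_smooth_lags Moving-average length (lags) applied to the
#'   cross-correlation before peak picking; counters peak wander from
#'   band-limited noise.
#' @param lag_prior_frac Width of the Gaussian preference for small shifts,
#'   as a fraction of the component's maximal shift (`NA` disables it).
#' @return Object of class `ride_config`.
#' @export
ride_config <- function(components = data.frame(
                          name = c("S", "C1", "C2"),
                          start_ms = c(0, 150, 300),
                          end_ms = c(250, 350, 700),
                          locked = c(TRUE, FALSE, FALSE),
                          stringsAsFactors = FALSE),
                        max_iterations = 20, tol_uV = 0.02,
                        xc_smooth_lags = 9, lag_prior_frac = NA) {
  stopifnot(all(components$end_ms > components$start_ms))
  structure(list(components = components, max_iterations = max_iterations,
                 tol_uV = tol_uV, xc_smooth_lags = xc_smooth_lags,
                 lag_prior_frac = lag_prior_frac), class = "ride_config")
}

## shift a channels x samples matrix right by `lat` samples, zero padding
.shift_mat <- function(m, lat) {
  if (lat == 0) return(m)
  ns <- ncol(m)
  out <- matrix(0, nrow(m), ns)
  if (lat > 0) {
    out[, (lat + 1):ns] <- m[, seq_len(ns - lat)]
  } else {
    out[, seq_len(ns + lat)] <- m[, (1 - lat):ns]
  }
  out
}

## channel-summed cross-correlation of M against template C at given lags
.xcorr_lags <- function(M, C, lags) {
  ns <- ncol(M)
  nf <- stats::nextn(ns + max(abs(lags)) + 1, 2)
  pad <- function(x) rbind(t(x), matrix(0, nf - ns, nrow(x)))
  FM <- stats::mvfft(pad(M))
  FC <- stats::mvfft(pad(C))
  prod <- rowSums(FM * Conj(FC))
  cc <- Re(stats::fft(prod, inverse = TRUE)) / nf
  sel <- ifelse(lags >= 0, lags + 1, nf + lags + 1)
  cc[sel]
}

## cosine-tapered window vector over the component's sample range
.comp_window <- function(times, start_ms, end_ms, taper_frac = 0.2) {
  w <- numeric(length(times))
  idx <- which(times * 1000 > start_ms & times * 1000 <= end_ms)
  if (!length(idx)) stop("component window outside epoch", call. = FALSE)
  k <- length(idx)
  tn <- max(1, floor(k * taper_frac))
  shape <- rep(1, k)
  ramp <- 0.5 * (1 - cos(pi * seq_len(tn) / (tn + 1)))
  shape[seq_len(tn)] <- ramp
  shape[k + 1 - seq_len(tn)] <- ramp
  w[idx] <- shape
  w
}

#' Decompose epochs into a stimulus-locked and latency-variable components
#'
#' Alternating estimation on a single condition's epochs: given latencies,
#' each free component waveform is the median (across trials) of the
#' residual after removing the other components' current contributions,
#' aligned to that component's latencies and windowed with cosine-tapered
#' edges; the stimulus-locked component is the mean residual over the full
#' epoch. Given waveforms, each free latency is the lag maximizing the
#' channel-summed cross-correlation between the trial residual and the
#' component, searched on the sample grid within half the component window,
#' ties broken toward the smaller absolute lag. Latencies are centred to
#' median 0 each iteration. Iteration stops when the waveform RMS change
#' drops below `tol_uV` or after `max_iterations` (then `converged = FALSE`
#' with a warning, never an error).
#'
#' With zero latency jitter the decomposition is an exact partition of the
#' plain trial average, so the reconstruction equals it.
#'
#' @param ep An `epoch_set` (single condition, >= 10 epochs) or a trials x
#'   channels x samples array.
#' @param config A [ride_config()].
#' @param times Epoch time axis (s); taken from `ep` when it is an
#'   `epoch_set`.
#' @return Object of class `ride_result`: `components` (named list of
#'   channels x samples matrices), `latencies_ms` (trials x free components,
#'   median 0), `reconstructed` (channels x samples), `iterations`,
#'   `converged`, `times`, `config`.
#' @export
ride_decompose <- function(ep, config = ride_config(), times = NULL) {
  if (inherits(ep, "epoch_set")) {
    X <- ep$epochs
    times <- ep$times
    ch_labels <- ep$channel_labels
  } else {
    X <- ep
    ch_labels <- dimnames(ep)[[2]]
    if (is.null(times)) stop("`times` required for array input")
  }
  n_tr <- dim(X)[1]
  if (n_tr < 10) stop("need at least 10 epochs", call. = FALSE)
  nch <- dim(X)[2]
  ns <- dim(X)[3]
  rate <- 1 / diff(times[1:2])
  comps <- config$components
  free <- which(!comps$locked)
  locked <- which(comps$locked)

  A <- apply(X, c(2, 3), mean)
  win <- lapply(seq_len(nrow(comps)), function(j) {
    .comp_window(times, comps$start_ms[j], comps$end_ms[j])
  })
  max_shift <- vapply(seq_len(nrow(comps)), function(j) {
    floor((comps$end_ms[j] - comps$start_ms[j]) / 2 / 1000 * rate)
  }, numeric(1))

  ## init: free components from the windowed plain average, latencies 0;
  ## during iteration the locked component is windowed like the others (so
  ## it cannot absorb the smeared average of a latency-variable component),
  ## and only the final locked estimate carries the full-epoch residue
  C <- vector("list", nrow(comps))
  names(C) <- comps$name
  for (j in free) C[[j]] <- A * rep(win[[j]], each = nch)
  lat <- matrix(0L, n_tr, nrow(comps))
  colnames(lat) <- comps$name
  resid0 <- A
  for (j in free) resid0 <- resid0 - C[[j]]
  for (j in locked) C[[j]] <- resid0 * rep(win[[j]], each = nch)

  sum_free_shifted <- function(t_i, except = 0) {
    acc <- matrix(0, nch, ns)
    for (k in free) {
      if (k == except) next
      acc <- acc + .shift_mat(C[[k]], lat[t_i, k])
    }
    acc
  }

  estimate_latencies <- function() {
    for (j in free) {
      lags <- seq.int(-max_shift[j], max_shift[j])
      lags <- lags[order(abs(lags), lags)]
      for (t_i in seq_len(n_tr)) {
        R <- X[t_i, , ] - C[[locked[1]]] - sum_free_shifted(t_i, except = j)
        xc <- .xcorr_lags(R, C[[j]], lags)
        ## smooth over neighbouring lags (bandpassed noise makes the raw
        ## cross-correlation peak wander) and softly prefer small shifts so
        ## residual structure at the window edges cannot capture the peak
        o <- order(lags)
        if (config$xc_smooth_lags > 1) {
          xc[o] <- moving_average(xc[o], as.integer(config$xc_smooth_lags))
        }
        if (!is.na(config$lag_prior_frac)) {
          xc <- xc *
            exp(-(lags / (max_shift[j] * config$lag_prior_frac))^2 / 2)
        }
        lat[t_i, j] <<- lags[which.max(xc)]
      }
      lat[, j] <<- lat[, j] - round_half_away(stats::median(lat[, j]))
    }
  }

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    C_old <- C
    ## (a) latencies given current waveforms
    estimate_latencies()
    ## (b) waveforms given latencies
    for (j in free) {
      aligned <- array(0, dim = c(n_tr, nch, ns))
      for (t_i in seq_len(n_tr)) {
        R <- X[t_i, , ] - C[[locked[1]]] - sum_free_shifted(t_i, except = j)
        aligned[t_i, , ] <- .shift_mat(R, -lat[t_i, j])
      }
      med <- apply(aligned, c(2, 3), stats::median)
      C[[j]] <- med * rep(win[[j]], each = nch)
    }
    ## stimulus-locked component: windowed mean residual during iteration
    Sacc <- matrix(0, nch, ns)
    for (t_i in seq_len(n_tr)) {
      Sacc <- Sacc + X[t_i, , ] - sum_free_shifted(t_i)
    }
    C[[locked[1]]] <- (Sacc / n_tr) * rep(win[[locked[1]]], each = nch)

    delta <- sqrt(mean(unlist(lapply(seq_along(C), function(j) {
      (C[[j]] - C_old[[j]])^2
    }))))
    if (delta < config$tol_uV) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("latency decomposition did not converge within ",
            config$max_iterations, " iterations")
  }

  ## final locked component: the full-epoch stimulus-locked residue, so the
  ## reconstruction covers the whole epoch (and equals the plain average
  ## exactly when all latencies are zero)
  Sacc <- matrix(0, nch, ns)
  for (t_i in seq_len(n_tr)) {
    Sacc <- Sacc + X[t_i, , ] - sum_free_shifted(t_i)
  }
  C[[locked[1]]] <- Sacc / n_tr

  recon <- Reduce(`+`, C)
  rownames(recon) <- ch_labels
  for (j in seq_along(C)) rownames(C[[j]]) <- ch_labels
  structure(list(
    components = C,
    latencies_ms = lat[, free, drop = FALSE] / rate * 1000,
    reconstructed = recon, iterations = iterations, converged = converged,
    times = times, config = config,
    channel_labels = ch_labels
  ), class = "ride_result")
}

#' Reconstruct the latency-corrected ERP from a decomposition
#'
#' Sum of all component waveforms, each placed at its median (zero) latency.
#'
#' @param result A `ride_result`.
#' @return Channels x samples matrix; attribute `"times"`.
#' @export
reconstruct_erp <- function(result) {
  m <- Reduce(`+`, result$components)
  rownames(m) <- result$channel_labels
  attr(m, "times") <- result$times
  m
}

#' @export
print.ride_result <- function(x, ...) {
  cat(sprintf(
    "<ride_result> %d components, %d trials, %d iterations (%sconverged)\n",
    length(x$components), nrow(x$latencies_ms), x$iterations,
    if (x$converged) "" else "NOT "))
  invisible(x)
}
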