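#' Extract reaction times from speech and visual events
#'
#' The reaction time to speak is the time between the visual presentation of
#' a word and the speaker's (refined) speech onset of that word. Each spoken
#' word yields one record for its speaker; sequence tags split the
#' post-critical-word positions into the two consecutive spoken sequences
#' (CW/CW+2/CW+4 vs CW+1/CW+3/CW+5). The preceding spoken word's refined
#' offset and the own visual onset are carried along for the overlap
#' exclusion rule.
#'
#' @param speech_events Data frame from [refine_session_events()] (columns
#'   `participant`, `trial`, `word_position`, `kind`, `time_s`, `source`).
#' @param visual_events Data frame with `trial`, `word_position`,
#'   `participant` (the speaker shown the word), `time_s`.
#' @param plan The session's `trial_plan` (for word lengths and congruency).
#' @return Data frame of class `rt_table`: `participant`, `trial`,
#'   `word_position`, `rt`, `word_length`, `congruency`, `sequence`,
#'   `visual_onset_s`, `prev_offset_s` (NA for word 1).
#' @export
extract_rts <- function(speech_events, visual_events, plan) {
  on <- speech_events[speech_events$kind == "onset", ]
  off <- speech_events[speech_events$kind == "offset", ]
  m <- merge(on, visual_events,
             by = c("trial", "word_position", "participant"),
             suffixes = c("_onset", "_visual"))
  prev <- off
  prev$word_position <- prev$word_position + 1L
  prev <- prev[, c("trial", "word_position", "time_s")]
  names(prev)[3] <- "prev_offset_s"
  m <- merge(m, prev, by = c("trial", "word_position"), all.x = TRUE)

  lens <- integer(nrow(m))
  congs <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    tr <- plan[plan$trial_index == m$trial[i], ]
    lens[i] <- nchar(tr[[paste0("word_", m$word_position[i])]])
    congs[i] <- tr[[paste0("congruency_p", m$participant[i])]]
  }
  out <- data.frame(
    participant = m$participant, trial = m$trial,
    word_position = m$word_position,
    rt = m$time_s_onset - m$time_s_visual,
    word_length = lens, congruency = congs,
    sequence = rt_sequence_tag(m$word_position),
    visual_onset_s = m$time_s_visual, prev_offset_s = m$prev_offset_s,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$trial, out$word_position), ]
  rownames(out) <- NULL
  class(out) <- c("rt_table", "data.frame")
  out
}

#' Apply the reaction-time exclusion rules
#'
#' Excludes RTs smaller than 300 ms or greater than 1000 ms (strict
#' inequalities: boundary values are kept) and words whose preceding spoken
#' word had not been terminated before the visual presentation (refined
#' offset of the previous word later than the own visual onset).
#'
#' @param table An `rt_table` (needs `prev_offset_s`/`visual_onset_s` for
#'   the overlap rule; rows with `NA` previous offset are not overlap-tested).
#' @param min_rt,max_rt Bounds in seconds.
#' @return List with `table` (input plus `excluded` flag and `reason`) and
#'   `report` (per-rule counts and fractions).
#' @export
filter_rts <- function(table, min_rt = 0.3, max_rt = 1.0) {
  too_fast <- table$rt < min_rt
  too_slow <- table$rt > max_rt
  overlap <- !is.na(table$prev_offset_s) &
    table$prev_offset_s > table$visual_onset_s
  table$excluded <- too_fast | too_slow | overlap
  table$reason <- ""
  table$reason[overlap] <- "preceding word not terminated"
  table$reason[too_slow] <- "rt > max"
  table$reason[too_fast] <- "rt < min"
  n <- nrow(table)
  report <- data.frame(
    rule = c("rt < min", "rt > max", "preceding word not terminated", "any"),
    n = c(sum(too_fast), sum(too_slow), sum(overlap), sum(table$excluded)),
    fraction = c(sum(too_fast), sum(too_slow), sum(overlap),
                 sum(table$excluded)) / n
  )
  list(table = table, report = report)
}

#' Fit the gamma GLMM for reaction times of one spoken-word sequence
#'
#' Gamma family with the inverse link; fixed effects congruency
#' (effects-coded) and spoken word position (ordered three-level factor
#' within the sequence); random intercepts for participant and for word
#' length (one level per integer letter count). Two separate models are
#' intended, one per sequence. Delegates to [lme4::glmer()]; coefficients
#' are reported on the link scale (not back-transformed) together with
#' back-transformed predicted mean RTs per congruency condition.
#'
#' @param table A filtered `rt_table` (rows with `excluded == TRUE` are
#'   dropped if the flag is present).
#' @param sequence `"cw_odd"` (CW+1/CW+3/CW+5) or `"cw_even"`
#'   (CW/CW+2/CW+4).
#' @param include_congruency,include_position Drop a fixed effect to obtain
#'   the reduced models for likelihood-ratio comparison.
#' @param nagq Integration accuracy passed to `glmer` (`nAGQ`); 0 is faster
#'   and adequate for large simulation batteries.
#' @return Object of class `glmm_fit`: `model`, `coefficients` (link
#'   scale), `loglik`, `predicted_means` (s, per congruency, averaged over
#'   positions), `converged`, `n`, `formula`.
#' @export
fit_rt_glmm <- function(table, sequence = c("cw_odd", "cw_even"),
                        include_congruency = TRUE, include_position = TRUE,
                        nagq = 1) {
  sequence <- match.arg(sequence)
  d <- table[table$sequence == sequence, , drop = FALSE]
  if (!is.null(d$excluded)) d <- d[!d$excluded, , drop = FALSE]
  if (nrow(d) < 10) stop("too few RTs for the GLMM", call. = FALSE)
  d$congruency <- factor(d$congruency, levels = c("congruent", "incongruent"))
  d$word_position <- factor(d$word_position, ordered = TRUE)
  d$participant <- factor(d$participant)
  d$word_length <- factor(d$word_length)
  stats::contrasts(d$congruency) <- stats::contr.sum(2)

  fixed <- c(if (include_congruency) "congruency",
             if (include_position) "word_position")
  rhs <- paste(c(fixed, "(1 | participant)", "(1 | word_length)"),
               collapse = " + ")
  form <- stats::as.formula(paste("rt ~", rhs))

  converged <- TRUE
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::Gamma(link = "inverse"),
                nAGQ = nagq,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )

  ## back-transformed predicted mean RT per congruency, averaged over the
  ## three word positions (fixed effects only)
  grid <- expand.grid(congruency = levels(d$congruency),
                      word_position = levels(d$word_position))
  grid$word_position <- factor(grid$word_position, ordered = TRUE,
                               levels = levels(d$word_position))
  stats::contrasts(grid$congruency) <- stats::contr.sum(2)
  pred <- tryCatch(
    stats::predict(fit, newdata = grid, re.form = NA, type = "response"),
    error = function(e) rep(NA_real_, nrow(grid))
  )
  pm <- tapply(pred, grid$congruency, mean)

  structure(list(
    model = fit,
    coefficients = lme4::fixef(fit),
    loglik = as.numeric(stats::logLik(fit)),
    df = attr(stats::logLik(fit), "df"),
    predicted_means = pm,
    converged = converged, messages = msgs,
    n = nrow(d), formula = form, sequence = sequence
  ), class = "glmm_fit")
}

#' Likelihood-ratio test between nested GLMM fits
#'
#' `chi2 = 2 * (logLik_full - logLik_reduced)` with df equal to the
#' parameter-count difference, as used to assess each fixed effect by
#' comparing the full model against the model without it.
#'
#' @param full,reduced `glmm_fit` objects (or `merMod` models) fitted to the
#'   same data, `reduced` nested in `full`.
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  ll <- function(x) {
    if (inherits(x, "glmm_fit")) {
      c(x$loglik, x$df)
    } else {
      l <- stats::logLik(x)
      c(as.numeric(l), attr(l, "df"))
    }
  }
  f <- ll(full)
  r <- ll(reduced)
  chi2 <- max(0, 2 * (f[1] - r[1]))
  df <- f[2] - r[2]
  if (df < 0) stop("`reduced` has more parameters than `full`", call. = FALSE)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> gamma/inverse GLMM, sequence %s, n = %d (%s)\n",
              x$sequence, x$n,
              if (x$converged) "converged" else "convergence flagged"))
  cat("fixed effects (link scale):\n")
  print(round(x$coefficients, 4))
  cat("predicted mean RT (s):\n")
  print(round(x$predicted_means, 4))
  invisible(x)
}
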