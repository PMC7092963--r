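#' Analysis windows and electrode sites for component statistics
#'
#' Mean-amplitude windows: P200 166-336 ms, N400 350-500 ms, P600
#' 500-650 ms, and the N100 effect window 60-160 ms. Sites: the four
#' midline electrodes (Fz, Cz, CPz, Pz) and the four lateral quadrants,
#' each averaged over its electrodes (left anterior Fp1, FC1, F7, C3; left
#' posterior CP1, CP5, P3, O1; right anterior Fp2, F8, FC2, C4; right
#' posterior CP2, CP6, P4, O2).
#'
#' @return Object of class `window_spec`: list with `windows_ms` (named list
#'   of `c(start, end)`) and `sites` (list `midline`, `quadrants`).
#' @export
window_spec <- function() {
  structure(list(
    windows_ms = list(P200 = c(166, 336), N400 = c(350, 500),
                      P600 = c(500, 650), N100 = c(60, 160)),
    sites = list(
      midline = list(Fz = "Fz", Cz = "Cz", CPz = "CPz", Pz = "Pz"),
      quadrants = list(
        left_anterior = c("Fp1", "FC1", "F7", "C3"),
        left_posterior = c("CP1", "CP5", "P3", "O1"),
        right_anterior = c("Fp2", "F8", "FC2", "C4"),
        right_posterior = c("CP2", "CP6", "P4", "O2"))
    )
  ), class = "window_spec")
}

#' Mean amplitude over a time window and electrode set
#'
#' Pure arithmetic mean over the window samples (half-open `(start, end]`)
#' and the listed electrodes. For an `epoch_set` a per-epoch vector is
#' returned; for an ERP matrix a scalar.
#'
#' @param x ERP matrix (channels x samples, with channel rownames) or an
#'   `epoch_set`.
#' @param window_ms `c(start, end)` in ms.
#' @param channels Electrode labels (default: all).
#' @param times Time axis in seconds (taken from the object if available).
#' @return Scalar (matrix input) or numeric vector (epoch input), microvolt.
#' @export
window_means <- function(x, window_ms, channels = NULL, times = NULL) {
  if (inherits(x, "epoch_set")) {
    times <- x$times
    labels <- x$channel_labels
    ci <- if (is.null(channels)) seq_along(labels) else match(channels, labels)
    if (anyNA(ci)) stop("unknown channel in `channels`", call. = FALSE)
    ti <- which(times * 1000 > window_ms[1] & times * 1000 <= window_ms[2])
    if (!length(ti)) stop("window outside epoch", call. = FALSE)
    return(vapply(seq_len(dim(x$epochs)[1]), function(j) {
      mean(x$epochs[j, ci, ti])
    }, numeric(1)))
  }
  if (is.null(times)) times <- attr(x, "times")
  if (is.null(times)) stop("`times` required for matrix input", call. = FALSE)
  labels <- rownames(x)
  ci <- if (is.null(channels)) seq_len(nrow(x)) else match(channels, labels)
  if (anyNA(ci)) stop("unknown channel in `channels`", call. = FALSE)
  ti <- which(times * 1000 > window_ms[1] & times * 1000 <= window_ms[2])
  if (!length(ti)) stop("window outside epoch", call. = FALSE)
  mean(x[ci, ti])
}

#' Subject x condition x site amplitude table for one component
#'
#' Builds the long-format table that feeds the repeated-measures ANOVA:
#' window-mean amplitudes per subject, condition and site (midline
#' electrodes, or quadrant averages computed per subject before the ANOVA).
#'
#' @param erps Nested list: `erps[[subject]][[condition]]` = ERP matrix
#'   (channels x samples with `"times"` attribute).
#' @param component Window name in [window_spec()].
#' @param sites `"midline"` or `"quadrants"`.
#' @param spec A [window_spec()].
#' @return Data frame: `subject`, `condition`, `site`, `amplitude`.
#' @export
roi_table <- function(erps, component = "N400", sites = "midline",
                      spec = window_spec()) {
  win <- spec$windows_ms[[component]]
  if (is.null(win)) stop("unknown component window: ", component)
  site_list <- spec$sites[[sites]]
  rows <- list()
  for (s in seq_along(erps)) {
    for (cond in names(erps[[s]])) {
      for (site in names(site_list)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, condition = cond, site = site,
          amplitude = window_means(erps[[s]][[cond]], win,
                                   site_list[[site]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Greenhouse-Geisser epsilon of a subject x level table
#'
#' Computed from the covariance of the orthonormally contrasted levels:
#' `eps = tr(M)^2 / ((k - 1) * tr(M %*% M))`. Bounded in
#' `[1/(k - 1), 1]`; equals 1 under compound symmetry.
#'
#' @param y Numeric matrix, subjects in rows, within-subject levels in
#'   columns (k >= 2).
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(y) {
  k <- ncol(y)
  if (k < 2) stop("need at least 2 levels", call. = FALSE)
  if (nrow(y) < 2) stop("need at least 2 subjects", call. = FALSE)
  C <- .orthonormal_contrasts(k)
  M <- t(C) %*% stats::cov(y) %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M * M))
}

.orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

#' Mauchly's sphericity test on a subject x level table
#'
#' @param y Numeric matrix, subjects x levels (k > 2; with k = 2 sphericity
#'   holds trivially and p = 1 is returned).
#' @return List with `W`, `chisq`, `df`, `p`.
#' @keywords internal
## Box/Anderson chi-square series approximation of Mauchly's W (the same
## second-order form base R's mauchly.test uses)
.mauchly_p <- function(W, q, n_df) {
  if (!is.finite(W) || W <= 0) return(0)
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * n_df)
  z <- -n_df * rho * log(W)
  f <- q * (q + 1) / 2 - 1
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * q + 2) /
    (288 * q^2 * n_df^2 * rho^2)
  stats::pchisq(z, f, lower.tail = FALSE) +
    w2 * (stats::pchisq(z, f + 4, lower.tail = FALSE) -
            stats::pchisq(z, f, lower.tail = FALSE))
}

mauchly_sphericity <- function(y) {
  k <- ncol(y)
  n <- nrow(y)
  if (k <= 2) return(list(W = 1, chisq = 0, df = 0, p = 1))
  C <- .orthonormal_contrasts(k)
  M <- t(C) %*% stats::cov(y) %*% C
  p_ <- k - 1
  W <- det(M) / (sum(diag(M)) / p_)^p_
  df <- p_ * (p_ + 1) / 2 - 1
  chisq <- -(n - 1) *
    (1 - (2 * p_^2 + p_ + 2) / (6 * p_ * (n - 1))) * log(W)
  list(W = W, chisq = chisq, df = df, p = .mauchly_p(W, p_, n - 1))
}

## effect-specific epsilon / Mauchly from the subject x cell matrix and the
## effect's orthonormal contrast matrix
.effect_sphericity <- function(cells, C_eff) {
  M <- t(C_eff) %*% stats::cov(cells) %*% C_eff
  q <- ncol(C_eff)
  eps <- sum(diag(M))^2 / (q * sum(M * M))
  n <- nrow(cells)
  if (q <= 1) return(list(eps = 1, mauchly_p = 1))
  W <- det(M) / (sum(diag(M)) / q)^q
  list(eps = eps, mauchly_p = .mauchly_p(W, q, n - 1))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One- or two-factor fully within-subject ANOVA from the textbook
#' sum-of-squares decomposition. For every effect with more than one
#' numerator df, Mauchly's test is run on the effect's contrast covariance;
#' when it indicates a sphericity violation (p < `mauchly_alpha`) the
#' reported p-value is Greenhouse-Geisser corrected while the original
#' degrees of freedom are reported alongside. Effect sizes are partial eta
#' squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame.
#' @param dv,subject,factor_a,factor_b Column names; `factor_b = NULL` gives
#'   the one-way design.
#' @param mauchly_alpha Sphericity-violation threshold (default .05).
#' @return Data frame of class `anova_table`: one row per effect with `F`,
#'   `df1`, `df2` (original), `epsilon`, `mauchly_p`, `p` (GG-corrected when
#'   violated), `p_uncorrected`, `pes` (partial eta squared), `gg_applied`.
#' @export
rm_anova <- function(data, dv = "amplitude", subject = "subject",
                     factor_a = "condition", factor_b = "site",
                     mauchly_alpha = 0.05) {
  data[[subject]] <- factor(data[[subject]])
  data[[factor_a]] <- factor(data[[factor_a]])
  if (!is.null(factor_b)) data[[factor_b]] <- factor(data[[factor_b]])
  subj <- levels(data[[subject]])
  a_lev <- levels(data[[factor_a]])
  b_lev <- if (is.null(factor_b)) "." else levels(data[[factor_b]])
  n <- length(subj)
  a <- length(a_lev)
  b <- length(b_lev)

  ## balanced subject x cell matrix (cells ordered b within a)
  cells <- matrix(NA_real_, n, a * b)
  for (si in seq_len(n)) {
    for (ai in seq_len(a)) {
      for (bi in seq_len(b)) {
        sel <- data[[subject]] == subj[si] & data[[factor_a]] == a_lev[ai]
        if (!is.null(factor_b)) sel <- sel & data[[factor_b]] == b_lev[bi]
        v <- data[[dv]][sel]
        if (length(v) != 1) {
          stop("unbalanced table: expected exactly one value per subject ",
               "x cell (found ", length(v), ")", call. = FALSE)
        }
        cells[si, (ai - 1) * b + bi] <- v
      }
    }
  }

  mu <- mean(cells)
  m_s <- rowMeans(cells)
  m_a <- vapply(seq_len(a), function(ai) {
    mean(cells[, (ai - 1) * b + seq_len(b)])
  }, numeric(1))
  m_b <- vapply(seq_len(b), function(bi) {
    mean(cells[, seq(bi, a * b, by = b)])
  }, numeric(1))
  m_ab <- matrix(colMeans(cells), a, b, byrow = TRUE)
  m_as <- vapply(seq_len(a), function(ai) {
    rowMeans(cells[, (ai - 1) * b + seq_len(b), drop = FALSE])
  }, numeric(n))                    # n x a
  m_bs <- vapply(seq_len(b), function(bi) {
    rowMeans(cells[, seq(bi, a * b, by = b), drop = FALSE])
  }, numeric(n))                    # n x b

  ss_a <- n * b * sum((m_a - mu)^2)
  ss_as <- b * sum(sweep(sweep(m_as, 2, m_a), 1, m_s - mu)^2)
  Ca <- .orthonormal_contrasts(a)
  out <- list()
  sph_a <- .effect_sphericity(m_as, Ca)
  out[[factor_a]] <- list(ss = ss_a, ss_err = ss_as, df1 = a - 1,
                          df2 = (a - 1) * (n - 1), sph = sph_a)

  if (!is.null(factor_b)) {
    ss_b <- n * a * sum((m_b - mu)^2)
    ss_bs <- a * sum(sweep(sweep(m_bs, 2, m_b), 1, m_s - mu)^2)
    Cb <- .orthonormal_contrasts(b)
    sph_b <- .effect_sphericity(m_bs, Cb)
    out[[factor_b]] <- list(ss = ss_b, ss_err = ss_bs, df1 = b - 1,
                            df2 = (b - 1) * (n - 1), sph = sph_b)

    dev <- m_ab
    for (ai in seq_len(a)) for (bi in seq_len(b)) {
      dev[ai, bi] <- m_ab[ai, bi] - m_a[ai] - m_b[bi] + mu
    }
    ss_ab <- n * sum(dev^2)
    ## three-way residual
    ss_abs <- 0
    for (si in seq_len(n)) for (ai in seq_len(a)) for (bi in seq_len(b)) {
      y <- cells[si, (ai - 1) * b + bi]
      ss_abs <- ss_abs + (y - m_ab[ai, bi] - m_as[si, ai] - m_bs[si, bi] +
                            m_a[ai] + m_b[bi] + m_s[si] - mu)^2
    }
    ## cells are ordered b-within-a, so kron(Ca, Cb) matches the cell order
    C_ab <- kronecker(Ca, Cb)
    sph_ab <- .effect_sphericity(cells, C_ab)
    out[[paste0(factor_a, ":", factor_b)]] <- list(
      ss = ss_ab, ss_err = ss_abs, df1 = (a - 1) * (b - 1),
      df2 = (a - 1) * (b - 1) * (n - 1), sph = sph_ab)
  }

  res <- do.call(rbind, lapply(names(out), function(nm) {
    e <- out[[nm]]
    Fv <- (e$ss / e$df1) / (e$ss_err / e$df2)
    p_unc <- stats::pf(Fv, e$df1, e$df2, lower.tail = FALSE)
    gg <- e$df1 > 1 && e$sph$mauchly_p < mauchly_alpha
    p <- if (gg) {
      stats::pf(Fv, e$df1 * e$sph$eps, e$df2 * e$sph$eps, lower.tail = FALSE)
    } else {
      p_unc
    }
    data.frame(effect = nm, F = Fv, df1 = e$df1, df2 = e$df2,
               epsilon = e$sph$eps, mauchly_p = e$sph$mauchly_p, p = p,
               p_uncorrected = p_unc, pes = e$ss / (e$ss + e$ss_err),
               gg_applied = gg, stringsAsFactors = FALSE)
  }))
  class(res) <- c("anova_table", "data.frame")
  res
}

#' First-word auditory N100 analysis
#'
#' Tests the attenuation of the auditory N100 over the first four heard
#' words of each trial: a word (4) x electrode (4, midline) repeated
#' measures ANOVA on the 60-160 ms mean amplitude, delegated to
#' [rm_anova()].
#'
#' @param table Long data frame with columns `subject`, `word` (1-4),
#'   `electrode` (midline labels), `amplitude` (the 60-160 ms window mean).
#' @return An `anova_table`.
#' @export
n100_word_position_analysis <- function(table) {
  rm_anova(table, dv = "amplitude", subject = "subject",
           factor_a = "word", factor_b = "electrode")
}
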