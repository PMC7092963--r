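make_erp <- function(fun, rate = 500, t0 = -0.5, t1 = 1.5) {
  times <- seq(t0 + 1 / rate, t1, by = 1 / rate)
  m <- matrix(rep(fun(times), each = 24), 24, byrow = FALSE)
  rownames(m) <- wbw_montage
  attr(m, "times") <- times
  m
}

test_that("window means are exact on constants, sinusoids and random data", {
  ## constant 2 uV: mean 2 for any window
  cst <- make_erp(function(t) rep(2, length(t)))
  expect_equal(window_means(cst, c(166, 336), "Cz"), 2)
  expect_equal(window_means(cst, c(-400, 1400)), 2)
  ## integer cycles of a zero-mean sinusoid average to ~0
  sine <- make_erp(function(t) sin(2 * pi * 10 * t))
  expect_lt(abs(window_means(sine, c(0, 1000), "Pz")), 1e-10)
  ## random data vs brute-force per-sample summation
  set.seed(2)
  m <- matrix(rnorm(24 * 1000), 24)
  rownames(m) <- wbw_montage
  times <- seq(-0.5 + 1 / 500, 1.5, by = 1 / 500)
  chans <- c("Fz", "CPz")
  got <- window_means(m, c(350, 500), chans, times)
  sel <- which(times * 1000 > 350 & times * 1000 <= 500)
  acc <- 0; k <- 0
  for (ch in match(chans, wbw_montage)) for (s in sel) {
    acc <- acc + m[ch, s]; k <- k + 1
  }
  expect_equal(got, unname(acc / k), tolerance = 1e-12)
  expect_error(window_means(m, c(350, 500), "nope", times), "unknown channel")
})

test_that("Greenhouse-Geisser epsilon matches the textbook formula", {
  ## compound symmetry: epsilon ~ 1
  set.seed(11)
  n <- 120; k <- 4
  subj <- rnorm(n, 0, 2)
  y_cs <- matrix(rnorm(n * k), n, k) + subj
  expect_gt(gg_epsilon(y_cs), 0.9)
  ## analytic lower bound 1/(k-1)
  y_worst <- cbind(rnorm(12), rnorm(12, 0, 1e-4), rnorm(12, 0, 1e-4),
                   rnorm(12, 0, 1e-4))
  expect_gte(gg_epsilon(y_worst) + 1e-12, 1 / 3)
  ## independent textbook oracle: epsilon from the double-centred covariance
  gg_oracle <- function(y) {
    S <- stats::cov(y)
    k <- ncol(S)
    dc <- S - outer(rowMeans(S), rep(1, k)) -
      outer(rep(1, k), colMeans(S)) + mean(S)
    sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
  }
  for (seed in 1:20) {
    y <- wordbyword:::with_seed(seed, {
      L <- matrix(rnorm(16), 4)
      matrix(rnorm(15 * 4), 15) %*% L
    })
    expect_equal(gg_epsilon(y), gg_oracle(y), tolerance = 1e-10)
  }
})

test_that("Mauchly's test agrees with the base-R implementation", {
  for (seed in 1:10) {
    y <- wordbyword:::with_seed(seed, {
      L <- matrix(rnorm(16), 4)
      matrix(rnorm(20 * 4), 20) %*% L
    })
    mine <- wordbyword:::mauchly_sphericity(y)
    fit <- stats::lm(y ~ 1)
    ## contrast against the orthonormal within-subject transformation
    ref <- stats::mauchly.test(fit, M = diag(4) - 1 / 4)
    ## base R uses the untransformed dimension in one term of the Box
    ## series; agreement is to approximation accuracy, not bit-exact
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-2)
    expect_equal(mine$W, unname(ref$statistic), tolerance = 1e-8)
  }
})

test_that("rm_anova reproduces anova.mlm on random two-factor tables", {
  for (seed in 1:8) {
    n <- 14; a <- 2; b <- 4
    dat <- wordbyword:::with_seed(seed, {
      d <- expand.grid(subject = 1:n, condition = paste0("c", 1:a),
                       site = paste0("s", 1:b))
      d$amplitude <- rnorm(nrow(d)) + rep(rnorm(n, 0, 1.5), a * b)
      d
    })
    mine <- rm_anova(dat)
    Y <- matrix(0, n, a * b)
    for (i in seq_len(nrow(dat))) {
      ai <- as.integer(factor(dat$condition))[i]
      bi <- as.integer(factor(dat$site))[i]
      Y[dat$subject[i], (ai - 1) * b + bi] <- dat$amplitude[i]
    }
    idata <- expand.grid(site = factor(paste0("s", 1:b)),
                         condition = factor(paste0("c", 1:a)))
    fit <- stats::lm(Y ~ 1)
    ref_int <- stats::anova(fit, idata = idata, X = ~ condition + site,
                            M = ~ condition * site, test = "Spherical")
    ref_a <- stats::anova(fit, idata = idata, X = ~ 1, M = ~ condition,
                          test = "Spherical")
    expect_equal(mine$F[mine$effect == "condition"],
                 ref_a[1, "F"], tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "condition:site"],
                 ref_int[1, "F"], tolerance = 1e-8)
    expect_equal(mine$p_uncorrected[mine$effect == "condition:site"],
                 ref_int[1, "Pr(>F)"], tolerance = 1e-8)
    ## my epsilon reproduces the oracle's GG-corrected p exactly
    ii <- mine$effect == "condition:site"
    p_gg_mine <- stats::pf(mine$F[ii], mine$df1[ii] * mine$epsilon[ii],
                           mine$df2[ii] * mine$epsilon[ii],
                           lower.tail = FALSE)
    expect_equal(p_gg_mine, ref_int[1, "G-G Pr"], tolerance = 1e-6)
  }
})

test_that("two-level single-factor F equals the squared paired t statistic", {
  for (seed in 1:10) {
    d <- wordbyword:::with_seed(seed, {
      data.frame(subject = rep(1:16, 2),
                 condition = rep(c("a", "b"), each = 16),
                 amplitude = rnorm(32))
    })
    res <- rm_anova(d, factor_b = NULL)
    x <- d$amplitude[d$condition == "a"]
    y <- d$amplitude[d$condition == "b"]
    tt <- stats::t.test(x, y, paired = TRUE)
    expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("partial eta squared stays in [0,1] and matches its definition", {
  set.seed(33)
  dat <- expand.grid(subject = 1:10, condition = c("x", "y"),
                     site = paste0("s", 1:4))
  dat$amplitude <- rnorm(nrow(dat)) +
    ifelse(dat$condition == "y", 0.8, 0)
  res <- rm_anova(dat)
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  ## identity pes = F*df1 / (F*df1 + df2)
  expect_equal(res$pes, res$F * res$df1 / (res$F * res$df1 + res$df2),
               tolerance = 1e-10)
  expect_true(all(res$epsilon >= 1 / (res$df1 + 1) - 1e-9 &
                    res$epsilon <= 1 + 1e-9))
})

test_that("unbalanced tables are rejected", {
  dat <- expand.grid(subject = 1:6, condition = c("x", "y"),
                     site = paste0("s", 1:4))
  dat$amplitude <- rnorm(nrow(dat))
  expect_error(rm_anova(dat[-3, ]), "unbalanced")
})

test_that("the first-word N100 analysis delegates to the generic ANOVA", {
  b <- fx_eeg_session()
  ep <- fx_heard_epochs(b)
  ## per-participant pseudo-subjects via split-half averaging of word 1-4
  ## heard epochs on the midline electrodes
  rows <- list()
  ws <- window_spec()
  for (p in 1:2) {
    psel <- ep$labels$trial %% 2 == (p - 1)  # split halves as subjects
    for (w in 1:4) {
      sub <- subset_epochs(ep, ep$labels$word_position == w & psel)
      erp <- average_epochs(sub)
      for (e in c("Fz", "Cz", "CPz", "Pz")) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = p, word = w, electrode = e,
          amplitude = window_means(erp, ws$windows_ms$N100, e, ep$times))
      }
    }
  }
  tab <- do.call(rbind, rows)
  ## too few subjects for inference; check structural delegation only
  res <- tryCatch(n100_word_position_analysis(tab), error = function(e) e)
  gen <- tryCatch(rm_anova(tab, dv = "amplitude", subject = "subject",
                           factor_a = "word", factor_b = "electrode"),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(gen, "error")
  } else {
    expect_identical(res, gen)
    ## planted first-word N100 gain: word 1 more negative than words 2-4
    m1 <- mean(tab$amplitude[tab$word == 1])
    m234 <- mean(tab$amplitude[tab$word > 1])
    expect_lt(m1, m234)
  }
})
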