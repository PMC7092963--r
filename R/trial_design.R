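#' Design specification for a dyadic word-by-word session
#'
#' Encodes the joint design constraints of the paradigm: trial count, the
#' fraction of trials that are incongruent for each participant, the fraction
#' started by participant 1, and how each participant's incongruent trials
#' are split between trials in which they perceive the critical word (CW,
#' word 8, always spoken by the non-starter) and trials in which they speak
#' it. The default reproduces the published design: 240 trials, 25%
#' incongruent per participant, starters balanced, and a 2:1
#' perceiving:speaking split of the incongruent trials (40 vs 20), so that
#' per participant the spoken-word sequences carry 80:40 and 100:20
#' expected:unexpected words.
#'
#' @param n_trials Even number of trials per session.
#' @param frac_incongruent Fraction of trials incongruent for each
#'   participant, in `[0, 1]`.
#' @param frac_starter_p1 Fraction of trials in which participant 1 reads
#'   word 1 (and therefore perceives the CW).
#' @param incongruent_split Integer vector `c(perceiving, speaking)`: how many
#'   of each participant's incongruent trials fall on perceived vs spoken
#'   CWs. Default splits `frac_incongruent * n_trials` 2:1.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(n_trials = 240, frac_incongruent = 0.25,
                        frac_starter_p1 = 0.5, incongruent_split = NULL) {
  if (n_trials %% 2 != 0) stop("n_trials must be even", call. = FALSE)
  if (frac_incongruent < 0 || frac_incongruent > 1) {
    stop("frac_incongruent must be in [0, 1]", call. = FALSE)
  }
  n_inc <- frac_incongruent * n_trials
  if (is.null(incongruent_split)) {
    incongruent_split <- c(perceiving = round(2 * n_inc / 3),
                           speaking = n_inc - round(2 * n_inc / 3))
  } else {
    incongruent_split <- c(perceiving = incongruent_split[[1]],
                           speaking = incongruent_split[[2]])
  }
  spec <- structure(list(
    n_trials = as.integer(n_trials),
    frac_incongruent = frac_incongruent,
    frac_starter_p1 = frac_starter_p1,
    incongruent_split = incongruent_split
  ), class = "design_spec")
  err <- .spec_infeasibility(spec)
  if (!is.null(err)) stop("infeasible design spec: ", err, call. = FALSE)
  spec
}

## returns NULL if feasible, otherwise a message naming the violated constraint
.spec_infeasibility <- function(spec) {
  n <- spec$n_trials
  n_inc <- spec$frac_incongruent * n
  if (abs(n_inc - round(n_inc)) > 1e-9) {
    return(sprintf("frac_incongruent * n_trials = %.3f is not an integer", n_inc))
  }
  n1 <- spec$frac_starter_p1 * n
  if (abs(n1 - round(n1)) > 1e-9) {
    return(sprintf("frac_starter_p1 * n_trials = %.3f is not an integer", n1))
  }
  sp <- spec$incongruent_split
  if (any(abs(sp - round(sp)) > 1e-9) || any(sp < 0)) {
    return("incongruent_split must be non-negative integers")
  }
  if (abs(sum(sp) - round(n_inc)) > 1e-9) {
    return(sprintf(
      "incongruent_split (%d + %d) does not sum to frac_incongruent * n_trials (%d)",
      round(sp[1]), round(sp[2]), round(n_inc)))
  }
  ## group capacity: a trial may be incongruent for at most one participant.
  ## In P1-starter trials, P1 perceives the CW and P2 speaks it, so that group
  ## must host P1's perceiving-incongruent and P2's speaking-incongruent trials.
  n1 <- round(n1)
  if (sp["perceiving"] + sp["speaking"] > n1) {
    return(sprintf(
      "incongruent trials needed in P1-starter group (%d) exceed its size (%d)",
      sp["perceiving"] + sp["speaking"], n1))
  }
  if (sp["perceiving"] + sp["speaking"] > n - n1) {
    return(sprintf(
      "incongruent trials needed in P2-starter group (%d) exceed its size (%d)",
      sp["perceiving"] + sp["speaking"], n - n1))
  }
  NULL
}

#' Built-in fixture lexicon of 13-word homonym sentences
#'
#' Each item is two sentences totalling 13 words with the homonym at word 4
#' and the critical word (CW) at word 8, plus one prime per homonym meaning
#' (`prime_a` congruent with the CW actually used, `prime_b` incongruent).
#' The first two items are the published German example items (piano/wing and
#' bench/bank); the rest are programmatically generated placeholder items of
#' matched structure and letter-count statistics, flagged by
#' `sentence_id` prefix `"synth"`.
#'
#' @param n Number of items to return (>= 2).
#' @param seed Seed for placeholder generation.
#' @return Data frame with columns `sentence_id`, `prime_a`, `prime_b`,
#'   `word_1` .. `word_13`.
#' @export
sentence_lexicon <- function(n = 240, seed = 1) {
  stopifnot(n >= 1)
  real <- data.frame(
    sentence_id = c("ex_fluegel", "ex_bank"),
    prime_a = c("Konzert", "Park"),
    prime_b = c("Engel", "Kredit"),
    rbind(
      c("Jana", "sieht", "den", "Flügel", "Sie", "berührt", "eine",
        "Taste", "und", "hört", "den", "reinen", "Klang"),
      c("Peter", "sucht", "eine", "Bank", "Er", "braucht", "etwas",
        "Ruhe", "um", "später", "ausgehen", "zu", "können")
    ),
    stringsAsFactors = FALSE
  )
  names(real)[4:16] <- paste0("word_", 1:13)
  if (n <= 2) return(real[seq_len(n), , drop = FALSE])

  n_syn <- n - 2L
  ## letter-count template per position (name verb det HOMONYM pron verb det
  ## CW conj verb det adj noun); the mean of ~5.3 letters puts the median
  ## word duration of the timing model at the paradigm-typical 0.54 s
  target_len <- c(5, 6, 3, 7, 3, 7, 4, 6, 4, 6, 4, 8, 6)
  syllables <- c("ba", "do", "ki", "lu", "me", "na", "po", "re", "sa", "ti",
                 "vo", "wu", "ze", "gri", "pla", "sto")
  make_word <- function(len) {
    w <- ""
    while (nchar(w) < len) w <- paste0(w, sample(syllables, 1))
    substr(w, 1, len)
  }
  with_seed(seed, {
    words <- matrix("", n_syn, 13)
    for (i in seq_len(n_syn)) {
      lens <- pmax(2, target_len + sample(-1:1, 13, replace = TRUE))
      words[i, ] <- vapply(lens, make_word, character(1))
      ## capitalize sentence-initial words (positions 1 and 5)
      for (j in c(1, 5)) {
        substr(words[i, j], 1, 1) <- toupper(substr(words[i, j], 1, 1))
      }
    }
    syn <- data.frame(
      sentence_id = sprintf("synth_%03d", seq_len(n_syn)),
      prime_a = vapply(rep(6, n_syn), make_word, character(1)),
      prime_b = vapply(rep(6, n_syn), make_word, character(1)),
      words, stringsAsFactors = FALSE
    )
    names(syn)[4:16] <- paste0("word_", 1:13)
    ## primes must differ within an item
    same <- syn$prime_a == syn$prime_b
    syn$prime_b[same] <- paste0(syn$prime_b[same], "x")
    rbind(real, syn)
  })
}

#' Generate a trial plan satisfying the dyadic design constraints
#'
#' Assigns sentences (without replacement), starters, and per-participant
#' congruency labels so that every count in the design spec is met exactly:
#' each participant is incongruent in `frac_incongruent` of trials, perceives
#' the CW in the non-started trials, and the incongruent trials split between
#' perceiving and speaking roles per `incongruent_split`. At most one
#' participant is incongruent in any trial. Trial order is randomized by
#' `seed`; the result is byte-identical for identical inputs.
#'
#' @param spec A [design_spec()].
#' @param sentences Sentence data frame as from [sentence_lexicon()] with at
#'   least `spec$n_trials` rows.
#' @param seed Integer seed.
#' @return Object of class `trial_plan`: a data frame with one row per trial
#'   (`trial_index`, `sentence_id`, `starter`, `congruency_p1`,
#'   `congruency_p2`, `cw_speaker`, `prime_p1`, `prime_p2`,
#'   `word_1`..`word_13`) and the spec stored as attribute `"spec"`.
#' @export
build_trial_plan <- function(spec, sentences = sentence_lexicon(spec$n_trials),
                             seed = 1) {
  stopifnot(inherits(spec, "design_spec"))
  err <- .spec_infeasibility(spec)
  if (!is.null(err)) stop("infeasible design spec: ", err, call. = FALSE)
  n <- spec$n_trials
  if (nrow(sentences) < n) {
    stop(sprintf("need at least %d sentences, got %d", n, nrow(sentences)),
         call. = FALSE)
  }
  n1 <- round(spec$frac_starter_p1 * n)
  sp <- round(spec$incongruent_split)

  with_seed(seed, {
    sent <- sentences[sample.int(nrow(sentences), n), , drop = FALSE]
    starter <- c(rep(1L, n1), rep(2L, n - n1))

    ## congruency role within each starter group:
    ## in P1-starter trials: P1 perceives CW, P2 speaks it
    role1 <- sample(c(rep("inc_perceiver", sp["perceiving"]),
                      rep("inc_speaker", sp["speaking"]),
                      rep("congruent", n1 - sum(sp))))
    role2 <- sample(c(rep("inc_perceiver", sp["perceiving"]),
                      rep("inc_speaker", sp["speaking"]),
                      rep("congruent", (n - n1) - sum(sp))))
    role <- c(role1, role2)

    cong_p1 <- cong_p2 <- rep("congruent", n)
    ## starter perceives the CW (word 8 is even, spoken by the non-starter)
    p1s <- starter == 1L
    cong_p1[p1s & role == "inc_perceiver"] <- "incongruent"
    cong_p2[p1s & role == "inc_speaker"] <- "incongruent"
    cong_p2[!p1s & role == "inc_perceiver"] <- "incongruent"
    cong_p1[!p1s & role == "inc_speaker"] <- "incongruent"

    ord <- sample.int(n)
    plan <- data.frame(
      trial_index = seq_len(n),
      sentence_id = sent$sentence_id[ord],
      starter = starter[ord],
      congruency_p1 = cong_p1[ord],
      congruency_p2 = cong_p2[ord],
      cw_speaker = ifelse(starter[ord] == 1L, 2L, 1L),
      prime_p1 = ifelse(cong_p1[ord] == "congruent",
                        sent$prime_a[ord], sent$prime_b[ord]),
      prime_p2 = ifelse(cong_p2[ord] == "congruent",
                        sent$prime_a[ord], sent$prime_b[ord]),
      sent[ord, paste0("word_", 1:13)],
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(plan, class = c("trial_plan", "data.frame"), spec = spec)
  })
}

#' Per-participant counts of a trial plan
#'
#' Pure recount over the trials: totals, congruent/incongruent, CW
#' producer/perceiver roles, and incongruent trials split by role.
#'
#' @param plan A `trial_plan` (or compatible data frame).
#' @return Data frame with one row per participant and columns `total`,
#'   `congruent`, `incongruent`, `producer_cw`, `perceiver_cw`,
#'   `incongruent_perceiving`, `incongruent_speaking`.
#' @export
plan_counts <- function(plan) {
  if (nrow(plan) == 0) {
    return(data.frame(participant = 1:2, total = 0L, congruent = 0L,
                      incongruent = 0L, producer_cw = 0L, perceiver_cw = 0L,
                      incongruent_perceiving = 0L, incongruent_speaking = 0L))
  }
  one <- function(p) {
    cong <- plan[[paste0("congruency_p", p)]]
    inc <- cong == "incongruent"
    speaks_cw <- plan$cw_speaker == p
    data.frame(
      participant = p,
      total = nrow(plan),
      congruent = sum(!inc),
      incongruent = sum(inc),
      producer_cw = sum(speaks_cw),
      perceiver_cw = sum(!speaks_cw),
      incongruent_perceiving = sum(inc & !speaks_cw),
      incongruent_speaking = sum(inc & speaks_cw)
    )
  }
  rbind(one(1L), one(2L))
}

#' Validate a trial plan against its invariants and a design spec
#'
#' @param plan A `trial_plan`.
#' @param spec A [design_spec()]; defaults to the one stored in the plan.
#' @return Character vector of violations (empty when the plan is valid);
#'   each entry names the offending trial or count.
#' @export
validate_plan <- function(plan, spec = attr(plan, "spec")) {
  v <- character(0)
  if (nrow(plan) == 0) return("plan is empty")
  both_inc <- plan$congruency_p1 == "incongruent" &
    plan$congruency_p2 == "incongruent"
  if (any(both_inc)) {
    v <- c(v, sprintf("trial %d incongruent for both participants",
                      plan$trial_index[both_inc]))
  }
  bad_cw <- plan$cw_speaker == plan$starter
  if (any(bad_cw)) {
    v <- c(v, sprintf("trial %d: cw_speaker equals starter",
                      plan$trial_index[bad_cw]))
  }
  if (anyDuplicated(plan$sentence_id)) {
    v <- c(v, "duplicated sentence assignment")
  }
  if (!is.null(spec)) {
    cnt <- plan_counts(plan)
    n <- spec$n_trials
    n_inc <- round(spec$frac_incongruent * n)
    sp <- round(spec$incongruent_split)
    expect <- data.frame(
      total = n, incongruent = n_inc,
      perceiver_cw = c(round(spec$frac_starter_p1 * n),
                       n - round(spec$frac_starter_p1 * n)),
      incongruent_perceiving = unname(sp["perceiving"]),
      incongruent_speaking = unname(sp["speaking"])
    )
    for (p in 1:2) {
      for (col in names(expect)) {
        if (cnt[[col]][p] != expect[[col]][p]) {
          v <- c(v, sprintf("participant %d: %s = %d, spec requires %d",
                            p, col, cnt[[col]][p], expect[[col]][p]))
        }
      }
    }
    if (nrow(plan) != n) v <- c(v, sprintf("plan has %d trials, spec %d",
                                           nrow(plan), n))
  }
  v
}

#' Write / read a trial plan as a tab-separated table
#'
#' @param plan A `trial_plan`.
#' @param path File path.
#' @return `write_trial_plan` returns `path` invisibly; `read_trial_plan`
#'   returns a `trial_plan` (without the spec attribute).
#' @export
write_trial_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_plan
#' @export
read_trial_plan <- function(path) {
  plan <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  structure(plan, class = c("trial_plan", "data.frame"))
}

#' @export
print.trial_plan <- function(x, ...) {
  cat(sprintf("<trial_plan> %d trials\n", nrow(x)))
  print(plan_counts(x))
  invisible(x)
}
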