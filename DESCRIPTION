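Package: wordbyword
Title: Analysis Pipeline for Dyadic Word-by-Word Spoken Interaction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing dyadic word-by-word
    interaction experiments in which two participants take turns reading aloud
    the words of a jointly produced sentence while EEG and audio are recorded
    from both. Provides constraint-satisfying trial-plan generation with
    per-participant prime congruency, a synthetic dyadic-session simulator
    (speech audio, dual-stream EEG with planted event-related potentials,
    voice-key markers, gamma-distributed reaction times, artifacts and packet
    loss), offline refinement of coarse voice-key speech onsets and offsets
    from the audio (envelope, mel-cepstrum and changepoint fusion), detection
    and correction of wireless-transmission data loss, ERP preprocessing and
    epoching, latency-corrected ERP reconstruction by iterative single-trial
    component decomposition, repeated-measures ANOVA with Greenhouse-Geisser
    correction, and gamma generalized linear mixed models for reaction times
    with likelihood-ratio model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
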