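#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic counter scheme so that pipeline stages can be re-run in
#' isolation with the same randomness. Kept below 2^31.
#'
#' @param master Master seed (integer).
#' @param stage Stage counter (small integer) or stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage)) %% 1000L
  }
  as.integer((as.numeric(master) * 7919 + as.numeric(stage)) %% 2147483629)
}

## ms <-> sample conversion, rounding half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a half-open time window (start, end] to sample offsets
#' @keywords internal
window_to_offsets <- function(window, rate) {
  lo <- round_half_away(window[1] * rate) + 1
  hi <- round_half_away(window[2] * rate)
  seq.int(lo, hi)
}

moving_average <- function(x, n) {
  if (n <= 1) return(x)
  k <- rep(1 / n, n)
  as.numeric(stats::filter(x, k, sides = 2, method = "convolution")) |>
    (\(y) { y[is.na(y)] <- 0; y })()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
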