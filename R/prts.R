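#' Generate a maximal-length pseudorandom ternary sequence over GF(3)
#'
#' Runs a linear-feedback shift register over the field GF(3) = \{0, 1, 2\}.
#' For a primitive feedback polynomial of degree `m` the state cycles through
#' every nonzero m-tuple exactly once, giving the maximal period `3^m - 1`.
#' The emitted symbol at each tick is the oldest state element.
#'
#' The recurrence for polynomial `x^m + a_1 x^(m-1) + ... + a_m` is
#' `s_t = -(a_1 s_(t-1) + ... + a_m s_(t-m)) mod 3`.
#'
#' @param degree LFSR degree `m` (positive integer).
#' @param feedback Integer vector `c(a_1, ..., a_m)` of polynomial
#'   coefficients over GF(3). Default `c(0, 2, 1)` is the primitive
#'   `x^3 + 2x + 1` used for the standard 26-step walking protocol.
#' @param initial_state Nonzero integer vector of length `degree` over
#'   \{0, 1, 2\}; default `c(0, ..., 0, 1)` (last element is the most
#'   recent state symbol).
#' @return Integer vector of one full period (`3^degree - 1` symbols) over
#'   \{0, 1, 2\}.
#' @examples
#' s <- generate_ternary_msequence(3)
#' length(s)          # 26
#' table(s)           # 0 appears 8 times; 1 and 2 appear 9 times each
#' @export
generate_ternary_msequence <- function(degree,
                                       feedback = c(0L, 2L, 1L),
                                       initial_state = c(rep(0L, degree - 1L), 1L)) {
  m <- as.integer(degree)
  stopifnot(m >= 1L, length(feedback) == m, length(initial_state) == m)
  a <- as.integer(feedback) %% 3L
  s0 <- as.integer(initial_state) %% 3L
  if (all(s0 == 0L)) {
    stop("initial_state must not be all-zero")
  }
  n_max <- 3L^m - 1L
  out <- integer(n_max)
  s <- s0
  for (t in seq_len(n_max)) {
    out[t] <- s[m]
    new <- (-sum(a * s[m:1])) %% 3L
    s <- c(s[-1L], new)
  }
  # a non-primitive polynomial returns the state to start before 3^m - 1 steps
  if (!all(s == s0) || has_shorter_period(out)) {
    stop("feedback polynomial is not primitive over GF(3): period < 3^", m, " - 1")
  }
  out
}

# TRUE if `x` repeats with some period strictly dividing length(x)
has_shorter_period <- function(x) {
  n <- length(x)
  for (p in seq_len(n %/% 2)) {
    if (n %% p == 0L && all(x == x[((seq_len(n) - 1L) %% p) + 1L])) {
      return(TRUE)
    }
  }
  FALSE
}

#' Build a PRTS walking-cadence schedule
#'
#' Maps the GF(3) field symbols to cadence offsets with the antisymmetric
#' convention `0 -> 0`, `1 -> +1`, `2 -> -1`, so the centered cadence signal is
#' antiperiodic over half a period and all even harmonics carry exactly zero
#' stimulus. Cadence at symbol `q` is `base_cadence + level_delta * q`.
#'
#' The warm-up is the tail of the sequence (the last `warmup_duration /
#' step_duration` symbols) prepended, so the analysed window starts with the
#' sequence already in steady state.
#'
#' @param symbols Field symbols over \{0, 1, 2\} from
#'   [generate_ternary_msequence()] (one full period).
#' @param step_duration Seconds each symbol is held (default 30).
#' @param base_cadence Middle cadence level in steps/min (default 105).
#' @param level_delta Cadence offset in steps/min (default 30, giving levels
#'   75/105/135).
#' @param warmup_duration Warm-up seconds of extra sequence prepended
#'   (default 300).
#' @return An object of class `prts_schedule` with fields `symbols` (mapped to
#'   \{-1, 0, +1\}), `step_duration`, `base_cadence`, `level_delta`,
#'   `warmup_duration`, `period` (seconds), and `cadence_levels`.
#' @export
build_prts_schedule <- function(symbols,
                                step_duration = 30,
                                base_cadence = 105,
                                level_delta = 30,
                                warmup_duration = 300) {
  if (level_delta <= 0) stop("level_delta must be positive")
  stopifnot(step_duration > 0, warmup_duration >= 0, all(symbols %in% 0:2))
  mapped <- c(0L, 1L, -1L)[symbols + 1L]
  n_warm <- warmup_duration / step_duration
  if (n_warm != round(n_warm)) {
    stop("warmup_duration must be a whole number of steps")
  }
  structure(
    list(
      symbols = mapped,
      step_duration = step_duration,
      base_cadence = base_cadence,
      level_delta = level_delta,
      warmup_duration = warmup_duration,
      period = length(mapped) * step_duration,
      cadence_levels = base_cadence + level_delta * c(-1L, 0L, 1L)
    ),
    class = "prts_schedule"
  )
}

#' @export
print.prts_schedule <- function(x, ...) {
  cat("PRTS schedule:", length(x$symbols), "symbols x", x$step_duration,
      "s =", x$period, "s period\n")
  cat("  cadence levels:", paste(x$cadence_levels, collapse = "/"),
      "steps/min; warm-up:", x$warmup_duration, "s\n")
  invisible(x)
}

#' Stimulated harmonic frequencies of a PRTS schedule
#'
#' The PRTS concentrates its power at odd multiples of the fundamental
#' `1/period`; even harmonics carry no stimulus and are excluded a priori.
#' Frequencies above `f_max` are dropped to stay within the band where the
#' aerobic response behaves as a linear first-order system.
#'
#' @param schedule A `prts_schedule`.
#' @param f_max Upper analysis frequency in Hz (default 0.008).
#' @return A list with `fundamental` (Hz), `harmonic_indices` (odd integers)
#'   and `frequencies` (Hz), class `harmonic_set`.
#' @export
stimulated_harmonics <- function(schedule, f_max = 0.008) {
  stopifnot(inherits(schedule, "prts_schedule"), schedule$period > 0)
  f0 <- 1 / schedule$period
  if (f_max < f0) stop("f_max is below the fundamental frequency ", signif(f0, 4), " Hz")
  k_max <- floor(f_max * schedule$period)
  idx <- seq(1L, max(1L, k_max), by = 2L)
  structure(
    list(fundamental = f0, harmonic_indices = idx, frequencies = idx * f0),
    class = "harmonic_set"
  )
}

#' Realize a PRTS schedule as a 1-Hz cadence series
#'
#' Piecewise-constant cadence, one sample per second, with step changes at
#' multiples of `step_duration`. With `include_warmup = TRUE` the tail of the
#' sequence is prepended as warm-up.
#'
#' @param schedule A `prts_schedule`.
#' @param include_warmup Prepend the warm-up samples? Default `FALSE`.
#' @return Numeric vector of cadence values in steps/min.
#' @export
cadence_signal <- function(schedule, include_warmup = FALSE) {
  stopifnot(inherits(schedule, "prts_schedule"))
  syms <- schedule$symbols
  if (include_warmup && schedule$warmup_duration > 0) {
    n_warm <- schedule$warmup_duration / schedule$step_duration
    syms <- c(utils::tail(schedule$symbols, n_warm), syms)
  }
  rep(schedule$base_cadence + schedule$level_delta * syms,
      each = schedule$step_duration)
}
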