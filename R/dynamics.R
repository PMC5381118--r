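#' Average two time-aligned PRTS repeats
#'
#' Point-wise mean of the two repeats to raise the signal-to-noise ratio,
#' yielding the single PRTS response per participant used for the
#' frequency-domain analysis.
#'
#' @param series_1,series_2 Numeric 1-Hz series, each exactly one PRTS period
#'   long and aligned to protocol start.
#' @return Numeric series of the same length.
#' @export
average_prts_repeats <- function(series_1, series_2) {
  if (length(series_1) != length(series_2)) {
    stop("repeat lengths differ: ", length(series_1), " vs ", length(series_2))
  }
  (series_1 + series_2) / 2
}

#' Harmonic gain spectrum of an input/output pair
#'
#' Removes the mean from each series, takes discrete Fourier amplitudes at
#' the stimulated harmonic bins (exact bins, since the series is one full
#' period at 1 Hz — no leakage, no window), and forms gains
#' `G_k = |Y_k| / |X_k|` normalised by the first-harmonic gain.
#'
#' @param input_series System input (hip acceleration), one period at 1 Hz.
#' @param output_series System output (measured or predicted VO2), same
#'   length.
#' @param harmonics A `harmonic_set` from [stimulated_harmonics()]; its
#'   fundamental must equal `1 / length(input_series)`.
#' @return A `gain_spectrum`: harmonic indices, frequencies, input/output
#'   amplitudes, gains and normalized gains (first harmonic identically 1).
#' @export
gain_spectrum <- function(input_series, output_series, harmonics) {
  n <- length(input_series)
  if (length(output_series) != n) stop("input/output length mismatch")
  stopifnot(inherits(harmonics, "harmonic_set"))
  if (abs(harmonics$fundamental - 1 / n) > 1e-12) {
    stop("harmonic set fundamental does not match series period")
  }
  xf <- stats::fft(input_series - mean(input_series))
  yf <- stats::fft(output_series - mean(output_series))
  k <- harmonics$harmonic_indices
  amp_x <- Mod(xf[k + 1L])
  amp_y <- Mod(yf[k + 1L])
  floor_x <- 1e-12 * max(Mod(xf))
  dead <- amp_x < floor_x
  if (any(dead)) {
    stop("no stimulus at harmonic ", paste(k[dead], collapse = ", "))
  }
  gain <- amp_y / amp_x
  structure(
    list(harmonic_indices = k, frequencies = harmonics$frequencies,
         input_amplitude = amp_x, output_amplitude = amp_y,
         gain = gain, normalized_gain = gain / gain[1L]),
    class = "gain_spectrum"
  )
}

#' Mean normalized gain (MNG)
#'
#' The mean of the normalized harmonic gains, in percent — the scalar index
#' of aerobic system temporal dynamics. Higher MNG means a faster aerobic
#' response. By default the first harmonic (normalized gain identically 1)
#' participates in the mean; set `include_first = FALSE` for the alternative
#' convention.
#'
#' @param spectrum A `gain_spectrum`.
#' @param include_first Include the first harmonic in the mean? Default
#'   `TRUE`.
#' @return An `mng_result` with `mng` (percent), `harmonics_used` and
#'   `include_first`.
#' @export
mean_normalized_gain <- function(spectrum, include_first = TRUE) {
  stopifnot(inherits(spectrum, "gain_spectrum"))
  g <- spectrum$normalized_gain
  k <- spectrum$harmonic_indices
  if (!include_first) {
    keep <- k != k[1L]
    g <- g[keep]
    k <- k[keep]
  }
  if (length(g) == 0L) stop("no harmonics left for the MNG mean")
  structure(list(mng = 100 * mean(g), harmonics_used = k,
                 include_first = include_first),
            class = "mng_result")
}

#' Closed-form MNG of a linear first-order system
#'
#' For first-order kinetics with time constant `tau`, the magnitude response
#' at frequency f is proportional to `1 / sqrt(1 + (2 pi f tau)^2)`, so the
#' normalized gain at harmonic k is
#' `sqrt((1 + (2 pi f1 tau)^2) / (1 + (2 pi fk tau)^2))`. This analytic value
#' is the oracle the measured pipeline MNG is checked against on simulated
#' participants.
#'
#' @param tau Time constant in seconds (`tau >= 0`).
#' @param harmonics A `harmonic_set`.
#' @param include_first Include the first harmonic in the mean? Default
#'   `TRUE`.
#' @return MNG in percent.
#' @export
first_order_mng_closed_form <- function(tau, harmonics, include_first = TRUE) {
  stopifnot(inherits(harmonics, "harmonic_set"), tau >= 0)
  f <- harmonics$frequencies
  g <- sqrt((1 + (2 * pi * f[1L] * tau)^2) / (1 + (2 * pi * f * tau)^2))
  if (!include_first) g <- g[-1L]
  100 * mean(g)
}

#' Per-participant MNG from measured and predicted VO2
#'
#' Extracts the two PRTS repeats from the frame, averages input (hip
#' acceleration) and each output across repeats, and computes two MNG values
#' from the same input spectrum: one with the measured VO2 as output, one
#' with the model predictions.
#'
#' @param frame A `sensor_frame` with `PRTS1` and `PRTS2` segments, each one
#'   PRTS period long.
#' @param predictions Predicted VO2 aligned with `frame$time`.
#' @param schedule The `prts_schedule` defining the period and harmonics.
#' @param f_max Upper analysis frequency in Hz (default 0.008).
#' @param include_first Passed to [mean_normalized_gain()].
#' @param input_channel System-input channel name (default `"Hacc"`).
#' @return List with `measured` and `predicted` `mng_result`s and the two
#'   `gain_spectrum` objects.
#' @export
participant_mng <- function(frame, predictions, schedule, f_max = 0.008,
                            include_first = TRUE, input_channel = "Hacc") {
  stopifnot(inherits(frame, "sensor_frame"), inherits(schedule, "prts_schedule"))
  if (length(predictions) != length(frame$time)) {
    stop("predictions must align with the frame's time grid")
  }
  i1 <- segment_indices(frame, "PRTS1")
  i2 <- segment_indices(frame, "PRTS2")
  if (length(i1) != schedule$period || length(i2) != schedule$period) {
    stop("PRTS segments must each be exactly one period (", schedule$period,
         " s) long")
  }
  harm <- stimulated_harmonics(schedule, f_max)
  input <- average_prts_repeats(frame$channels[[input_channel]][i1],
                                frame$channels[[input_channel]][i2])
  out_meas <- average_prts_repeats(frame$channels$VO2[i1], frame$channels$VO2[i2])
  out_pred <- average_prts_repeats(predictions[i1], predictions[i2])
  sp_meas <- gain_spectrum(input, out_meas, harm)
  sp_pred <- gain_spectrum(input, out_pred, harm)
  list(measured = mean_normalized_gain(sp_meas, include_first),
       predicted = mean_normalized_gain(sp_pred, include_first),
       spectrum_measured = sp_meas, spectrum_predicted = sp_pred)
}
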