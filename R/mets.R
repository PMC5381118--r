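#' Convert oxygen uptake to metabolic equivalents
#'
#' One MET corresponds to 3.5 ml O2 per minute per kg body mass by
#' convention; the constant is exposed for sensitivity analyses.
#'
#' @param vo2 VO2 in ml/min/kg, non-negative.
#' @param met_constant ml/min/kg per MET (default 3.5).
#' @return METS values.
#' @export
vo2_to_mets <- function(vo2, met_constant = 3.5) {
  if (any(vo2 < 0, na.rm = TRUE)) stop("VO2 must be non-negative")
  vo2 / met_constant
}

#' Resting metabolic rate from the resting segment
#'
#' Mean of a 60-sample window within the rest segment; by default the last
#' 60 s, when the participant has settled.
#'
#' @param vo2_series 1-Hz VO2 series in ml/min/kg.
#' @param rest_indices Integer indices of the rest segment within the series.
#' @param window_s Averaging window in seconds (default 60).
#' @return RMR in ml/min/kg.
#' @export
resting_metabolic_rate <- function(vo2_series, rest_indices, window_s = 60L) {
  if (length(rest_indices) < window_s) {
    stop("rest segment shorter than ", window_s, " s")
  }
  win <- utils::tail(rest_indices, window_s)
  mean(vo2_series[win])
}

#' Cluster samples into metabolic-intensity bands
#'
#' Bands follow the activity-intensity convention with half-open edges so
#' 3.9 -> light and 4.0 -> moderate deterministically: rest below 2 METS,
#' light \[2, 4), moderate \[4, 6), excluded at 6 METS and above (vigorous
#' activity is excluded a priori).
#'
#' @param mets Numeric METS series, finite.
#' @return Factor with levels `rest`, `light`, `moderate`, `excluded`.
#' @export
cluster_intensity <- function(mets) {
  stopifnot(all(is.finite(mets)))
  cut(mets, breaks = c(-Inf, 2, 4, 6, Inf), right = FALSE,
      labels = c("rest", "light", "moderate", "excluded"))
}

#' Per-cluster METS summary for measured vs predicted VO2
#'
#' Clusters samples by the measured METS and reports, per cluster, the mean
#' measured and predicted METS plus sample counts, alongside the excluded
#' fraction and, per the resting cluster, both the 60-s RMR estimate and the
#' mean over all rest-labelled samples.
#'
#' @param vo2_measured,vo2_predicted 1-Hz VO2 series in ml/min/kg.
#' @param rest_indices Indices of the annotated rest segment (for the RMR
#'   estimate); `NULL` to skip.
#' @param met_constant ml/min/kg per MET (default 3.5).
#' @return An `intensity_profile`: cluster table, labels, excluded fraction,
#'   and RMR estimates.
#' @export
intensity_profile <- function(vo2_measured, vo2_predicted,
                              rest_indices = NULL, met_constant = 3.5) {
  stopifnot(length(vo2_measured) == length(vo2_predicted))
  mets_m <- vo2_to_mets(pmax(vo2_measured, 0), met_constant)
  mets_p <- vo2_to_mets(pmax(vo2_predicted, 0), met_constant)
  labels <- cluster_intensity(mets_m)
  tab <- data.frame(
    cluster = levels(labels),
    n_samples = as.integer(table(labels)),
    mets_measured_mean = as.numeric(tapply(mets_m, labels, mean)),
    mets_predicted_mean = as.numeric(tapply(mets_p, labels, mean))
  )
  rmr <- if (!is.null(rest_indices)) {
    resting_metabolic_rate(vo2_measured, rest_indices)
  } else {
    NA_real_
  }
  structure(
    list(clusters = tab, labels = labels,
         excluded_fraction = mean(labels == "excluded"),
         rmr_vo2 = rmr,
         rmr_vo2_all_rest = mean(vo2_measured[labels == "rest"])),
    class = "intensity_profile"
  )
}
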