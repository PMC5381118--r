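#' Pearson correlation with p-value
#'
#' Standard product-moment coefficient with the two-sided p-value from the
#' t transform (via [stats::cor.test()]). Note that p-values on 1-Hz
#' physiological series are not corrected for autocorrelation and should be
#' read as descriptive.
#'
#' @param a,b Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance in at least one input")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Differences follow the measured-minus-predicted sign convention, so a
#' predictor that underestimates gives a positive bias. Limits of agreement
#' are `bias +/- 1.96 * SD` with the sample (n-1) standard deviation; the
#' same `1.96 * SD` half-width is reported as the interval around the bias.
#' The bias is compared with the equality line (bias = 0) by a one-sample
#' Student t-test.
#'
#' @param measured,predicted Numeric vectors of equal length (>= 3).
#' @return An `agreement_report`: `r`, `p_r`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `ci95_halfwidth`, `t_bias`, `p_bias`, `n`, `degenerate`.
#' @export
bland_altman <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 3L)
  d <- measured - predicted
  bias <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    t_bias <- NA_real_
    p_bias <- NA_real_
  } else {
    tt <- stats::t.test(d, mu = 0)
    t_bias <- unname(tt$statistic)
    p_bias <- tt$p.value
  }
  cor_ok <- stats::var(measured) > 0 && stats::var(predicted) > 0
  r <- if (cor_ok) pearson_r(measured, predicted) else list(r = NA_real_, p = NA_real_)
  structure(
    list(r = r$r, p_r = r$p, bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         ci95_halfwidth = 1.96 * sd_d, t_bias = t_bias, p_bias = p_bias,
         n = length(d), degenerate = degenerate),
    class = "agreement_report"
  )
}

#' Relative-frequency histogram of the prediction error
#'
#' @param measured,predicted Numeric vectors of equal length.
#' @param n_bins Number of equal-width bins (>= 1).
#' @return List with `bin_edges` and `relative_frequencies` (summing to 1).
#' @export
error_distribution <- function(measured, predicted, n_bins = 20L) {
  stopifnot(n_bins >= 1L, length(measured) == length(predicted))
  d <- measured - predicted
  rng <- range(d)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  list(bin_edges = edges, relative_frequencies = counts / length(d))
}

#' Full per-segment validation report for a cross-validated cohort
#'
#' Validates the held-out predictions against the raw (unfiltered) measured
#' VO2, separately for the activities-of-daily-living and PRTS segments, at
#' group level (all samples pooled) and per participant (mean +/- SD of the
#' per-participant statistics). Also compares the MNG computed from predicted
#' VO2 against the MNG from measured VO2, and tabulates the METS clusters.
#'
#' @param cohort A simulated or loaded cohort: list of per-participant
#'   entries, each with `frame` (a `sensor_frame`) and `features` (output of
#'   [build_feature_matrix()] on the full frame).
#' @param ensemble The fitted `oxydyn_ensemble` from [loso_cv()].
#' @param schedule The `prts_schedule` used in the protocol.
#' @param f_max Upper harmonic frequency (default 0.008 Hz).
#' @param include_first MNG convention flag (default `TRUE`).
#' @return A `study_report` list: `adl`, `prts` and `mng` agreement blocks,
#'   `per_participant` data frame, `mets` cluster table, and the raw MNG
#'   pairs.
#' @export
study_report <- function(cohort, ensemble, schedule, f_max = 0.008,
                         include_first = TRUE) {
  stopifnot(inherits(ensemble, "oxydyn_ensemble"))
  ids <- vapply(cohort, `[[`, "", "id")
  stopifnot(setequal(ids, ensemble$fold_participant_ids))

  per <- vector("list", length(cohort))
  pooled <- list(adl_m = c(), adl_p = c(), prts_m = c(), prts_p = c())
  mng_m <- mng_p <- numeric(length(cohort))

  for (i in seq_along(cohort)) {
    entry <- cohort[[i]]
    frame <- entry$frame
    feats <- entry$features
    k <- which(ensemble$fold_participant_ids == entry$id)
    pred <- predict_forest(ensemble$forests[[k]], feats$X)

    missing <- setdiff(c("ADL", "PRTS1", "PRTS2", "REST"),
                       unique(frame$segments$label))
    if (length(missing)) stop("participant ", entry$id,
                              " missing segments: ",
                              paste(missing, collapse = ", "))

    in_frame <- match(feats$time, frame$time)
    loc <- function(lbl) which(in_frame %in% segment_indices(frame, lbl))
    adl <- loc("ADL")
    prts <- loc(c("PRTS1", "PRTS2"))

    # reference is the raw measured VO2, not the filtered training target
    a_m <- feats$y_raw[adl]; a_p <- pred[adl]
    p_m <- feats$y_raw[prts]; p_p <- pred[prts]
    pooled$adl_m <- c(pooled$adl_m, a_m); pooled$adl_p <- c(pooled$adl_p, a_p)
    pooled$prts_m <- c(pooled$prts_m, p_m); pooled$prts_p <- c(pooled$prts_p, p_p)

    pred_frame <- rep(NA_real_, length(frame$time))
    pred_frame[in_frame] <- pred
    mng <- participant_mng(frame, pred_frame, schedule, f_max, include_first)
    mng_m[i] <- mng$measured$mng
    mng_p[i] <- mng$predicted$mng

    ba_adl <- bland_altman(a_m, a_p)
    ba_prts <- bland_altman(p_m, p_p)
    per[[i]] <- data.frame(
      participant_id = entry$id,
      r_adl = ba_adl$r, bias_adl = ba_adl$bias,
      r_prts = ba_prts$r, bias_prts = ba_prts$bias,
      mng_measured_pct = mng_m[i], mng_predicted_pct = mng_p[i]
    )
  }

  per <- do.call(rbind, per)
  mets <- intensity_profile(pooled$adl_m, pooled$adl_p)

  structure(
    list(
      adl = bland_altman(pooled$adl_m, pooled$adl_p),
      prts = bland_altman(pooled$prts_m, pooled$prts_p),
      # MNG agreement needs >= 3 participants for the t-test and correlation
      mng = if (length(mng_m) >= 3L) bland_altman(mng_m, mng_p) else
        list(r = NA_real_, bias = mean(mng_m - mng_p), n = length(mng_m)),
      per_participant = per,
      per_participant_mean = colMeans(per[, -1L]),
      per_participant_sd = apply(per[, -1L], 2L, stats::sd),
      mets = mets,
      mng_measured = mng_m, mng_predicted = mng_p
    ),
    class = "study_report"
  )
}
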