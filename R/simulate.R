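#' Default generative parameters for one synthetic participant
#'
#' First-order cardiorespiratory kinetics driven by walking cadence.
#' `static_gain` defaults keep the PRTS cadence peaks below 6 METS, matching
#' the light-to-moderate intensity envelope of realistic daily activities.
#'
#' @param tau_vo2 VO2 time constant in seconds.
#' @param static_gain VO2 gain in ml/min/kg per step/min of cadence.
#' @param delay Pure transport delay in seconds (default 0).
#' @param vo2_rest Resting VO2 in ml/min/kg.
#' @param tau_hr Heart-rate time constant in seconds.
#' @param hr_rest Resting heart rate in bpm.
#' @param hr_gain HR gain in bpm per step/min.
#' @param ve_per_vo2 Minute-ventilation coupling, L/min per ml/min/kg of
#'   noise-free VO2.
#' @param bf_base,bf_gain Breathing frequency baseline (breaths/min) and gain
#'   per ml/min/kg of VO2 excess.
#' @param hacc_per_cadence Hip acceleration in g per step/min.
#' @param noise_sd Named per-channel Gaussian noise SDs.
#' @param breath_interval_mean Mean inter-breath interval in seconds for the
#'   breath-by-breath VO2 sampling emulation.
#' @param seed Integer seed for this participant's noise streams.
#' @return A `sim_params` list.
#' @export
sim_params <- function(tau_vo2 = 35, static_gain = 0.105, delay = 0,
                       vo2_rest = 3.7, tau_hr = 28, hr_rest = 65,
                       hr_gain = 0.5, ve_per_vo2 = 2.2, bf_base = 14,
                       bf_gain = 1.6, hacc_per_cadence = 0.008,
                       noise_sd = c(VO2 = 1.5, HR = 2, VE = 1.5, BF = 2,
                                    Hacc = 0.05, CAD = 1),
                       breath_interval_mean = 3, seed = 1L) {
  stopifnot(tau_vo2 >= 0, tau_hr >= 0, vo2_rest > 0, all(noise_sd >= 0),
            breath_interval_mean > 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Default activities-of-daily-living script
#'
#' Labelled blocks (sitting, organizing a shelf, carrying objects, stairs,
#' self-paced walking, sitting at a computer) expressed as cadence-equivalent
#' excitation levels in steps/min, chosen so the resulting METS populate the
#' rest, light and moderate bands.
#'
#' @param block_duration Seconds per block (default 200).
#' @return Data frame `activity, u, duration_s`.
#' @export
default_adl_script <- function(block_duration = 200) {
  data.frame(
    activity = c("sit", "shelf", "carry", "stairs", "walk", "computer"),
    u = c(0, 45, 65, 115, 95, 5),
    duration_s = block_duration
  )
}

# exact exponential-hold update of dx/dt = (target - x) / tau at 1 Hz;
# tau = 0 degenerates to instantaneous tracking
first_order_response <- function(u, tau, x0) {
  n <- length(u)
  x <- numeric(n)
  x[1L] <- x0
  if (tau == 0) return(u)
  a <- exp(-1 / tau)
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- a * x[t] + (1 - a) * u[t]
  }
  x
}

shift_delay <- function(u, delay, fill) {
  d <- round(delay)
  if (d <= 0) return(u)
  c(rep(fill, d), u[seq_len(length(u) - d)])
}

#' Simulate one synthetic participant
#'
#' Builds the full session timeline - rest, warm-up + first PRTS repeat,
#' simulated daily activities, warm-up + second PRTS repeat - and drives
#' first-order VO2 and HR kinetics with the cadence-equivalent excitation.
#' Minute ventilation and breathing frequency are coupled to the noise-free
#' VO2; hip acceleration is piecewise-proportional to cadence. VO2 is sampled
#' at irregular breath times (exponential inter-breath intervals) and all
#' channels get Gaussian measurement noise before the standard resampling
#' path rebuilds the 1-Hz frame, so the preprocessing pipeline is exercised
#' end to end.
#'
#' @param params A `sim_params`.
#' @param schedule A `prts_schedule`.
#' @param adl_script Data frame from [default_adl_script()].
#' @param rest_duration Leading rest seconds (default 300).
#' @param breath_sampling Emulate breath-by-breath VO2 sampling? `FALSE`
#'   records VO2 directly on the 1-Hz grid (for noise-free oracle tests).
#' @return List with `frame` (a `sensor_frame`), `truth` (noise-free series,
#'   parameters, and closed-form true MNG) and `id` (`NA`, set by
#'   [simulate_cohort()]).
#' @export
simulate_participant <- function(params, schedule,
                                 adl_script = default_adl_script(),
                                 rest_duration = 300,
                                 breath_sampling = TRUE) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "prts_schedule"))
  prts_cad <- cadence_signal(schedule, include_warmup = TRUE)
  n_warm <- schedule$warmup_duration
  n_prts <- schedule$period

  adl_u <- rep(adl_script$u, times = adl_script$duration_s)
  u <- c(rep(0, rest_duration),           # rest
         prts_cad,                        # warm-up + PRTS1 (cadence = excitation)
         adl_u,                           # ADL
         prts_cad)                        # warm-up + PRTS2
  n <- length(u)
  t_grid <- seq(0, n - 1L)

  p1_start <- rest_duration + n_warm
  adl_start <- p1_start + n_prts
  p2_start <- adl_start + length(adl_u) + n_warm
  segments <- data.frame(
    label = c("REST", "PRTS1", "ADL", "PRTS2"),
    start_s = c(0, p1_start, adl_start, p2_start),
    end_s = c(rest_duration, p1_start + n_prts, adl_start + length(adl_u),
              p2_start + n_prts)
  )

  u_del <- shift_delay(u, params$delay, 0)
  vo2_clean <- first_order_response(params$vo2_rest + params$static_gain * u_del,
                                    params$tau_vo2, params$vo2_rest)
  hr_clean <- first_order_response(params$hr_rest + params$hr_gain * u_del,
                                   params$tau_hr, params$hr_rest)
  ve_clean <- params$ve_per_vo2 * vo2_clean
  bf_clean <- params$bf_base + params$bf_gain * (vo2_clean - params$vo2_rest)
  hacc_clean <- params$hacc_per_cadence * u
  cad_clean <- u

  harm <- stimulated_harmonics(schedule)
  truth <- list(
    params = params,
    vo2 = vo2_clean, hr = hr_clean, ve = ve_clean, bf = bf_clean,
    hacc = hacc_clean, cadence = cad_clean, time = t_grid,
    mng_true = first_order_mng_closed_form(params$tau_vo2, harm)
  )

  set.seed(params$seed)
  sd <- params$noise_sd
  channels <- list(
    HR = raw_channel("HR", t_grid, hr_clean + stats::rnorm(n, 0, sd[["HR"]])),
    VE = raw_channel("VE", t_grid, pmax(ve_clean + stats::rnorm(n, 0, sd[["VE"]]), 0)),
    BF = raw_channel("BF", t_grid, pmax(bf_clean + stats::rnorm(n, 0, sd[["BF"]]), 0)),
    Hacc = raw_channel("Hacc", t_grid, pmax(hacc_clean + stats::rnorm(n, 0, sd[["Hacc"]]), 0)),
    CAD = raw_channel("CAD", t_grid, pmax(cad_clean + stats::rnorm(n, 0, sd[["CAD"]]), 0))
  )
  if (breath_sampling) {
    gaps <- stats::rexp(ceiling(2 * n / params$breath_interval_mean),
                        rate = 1 / params$breath_interval_mean)
    bt <- c(0, cumsum(pmax(gaps, 0.3)))
    bt <- bt[bt <= n - 1L]
    if (utils::tail(bt, 1L) < n - 1L) bt <- c(bt, n - 1L)
    vo2_bt <- stats::approx(t_grid, vo2_clean, xout = bt)$y
    vo2_vals <- pmax(vo2_bt + stats::rnorm(length(bt), 0, sd[["VO2"]]), 0.1)
    channels$VO2 <- raw_channel("VO2", bt, vo2_vals)
  } else {
    channels$VO2 <- raw_channel("VO2", t_grid,
                                pmax(vo2_clean + stats::rnorm(n, 0, sd[["VO2"]]), 0.1))
  }

  frame <- synchronize_resample(channels, segments)
  list(frame = frame, truth = truth, id = NA_character_)
}

#' Simulate a synthetic study cohort
#'
#' Draws participant-specific kinetics from realistic ranges (time constants
#' spanning fit to slower aerobic responses) with a participant-indexed
#' random substream, so any single participant can be regenerated
#' bit-identically from the cohort seed.
#'
#' @param n Number of participants (default 16).
#' @param tau_range VO2 time-constant range in seconds (default `c(20, 60)`).
#' @param seed Cohort root seed.
#' @param schedule PRTS schedule; default the standard 26-symbol, 30-s-step,
#'   75/105/135 steps/min protocol with 300-s warm-up.
#' @param noise_scale Multiplier on every channel's default noise SD
#'   (0 gives noise-free participants for oracle tests).
#' @param ... Passed to [simulate_participant()].
#' @return A `sim_cohort`: list of participant entries (`frame`, `truth`,
#'   `features`, `id`) with attribute `schedule`.
#' @export
simulate_cohort <- function(n = 16L, tau_range = c(20, 60), seed = 1L,
                            schedule = NULL, noise_scale = 1, ...) {
  stopifnot(n >= 2L)
  if (is.null(schedule)) {
    schedule <- build_prts_schedule(generate_ternary_msequence(3))
  }
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2L, n)
  taus <- stats::runif(n, tau_range[1L], tau_range[2L])
  gains <- stats::runif(n, 0.095, 0.115)
  rests <- stats::runif(n, 3.2, 4.2)
  tau_hrs <- pmax(stats::runif(n, 0.7, 0.9) * taus, 5)
  hr_rests <- stats::runif(n, 58, 74)
  ve_cpl <- stats::runif(n, 2.0, 2.4)

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    nsd <- noise_scale * c(VO2 = 1.5, HR = 2, VE = 1.5, BF = 2,
                           Hacc = 0.05, CAD = 1)
    p <- sim_params(tau_vo2 = taus[i], static_gain = gains[i],
                    vo2_rest = rests[i], tau_hr = tau_hrs[i],
                    hr_rest = hr_rests[i], ve_per_vo2 = ve_cpl[i],
                    noise_sd = nsd, seed = sub_seeds[i])
    entry <- simulate_participant(p, schedule, ...)
    entry$id <- sprintf("P%02d", i)
    entry$features <- build_feature_matrix(entry$frame)
    cohort[[i]] <- entry
  }
  structure(cohort, schedule = schedule, seed = seed, class = "sim_cohort")
}

#' Stack a cohort's feature matrices for cross-validated training
#'
#' Rows are restricted to the annotated segments (both PRTS repeats, the
#' daily-activity block and rest) of every participant.
#'
#' @param cohort A `sim_cohort`.
#' @param segments Segment labels to keep (default all four).
#' @return List with `X`, `y` (filtered target), `y_raw`, `participant_id`.
#' @export
cohort_training_data <- function(cohort,
                                 segments = c("PRTS1", "PRTS2", "ADL", "REST")) {
  parts <- lapply(cohort, function(entry) {
    keep <- which(match(entry$features$time, entry$frame$time) %in%
                    segment_indices(entry$frame, segments))
    list(X = entry$features$X[keep, , drop = FALSE],
         y = entry$features$y[keep],
         y_raw = entry$features$y_raw[keep],
         id = rep(entry$id, length(keep)))
  })
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")),
       y_raw = unlist(lapply(parts, `[[`, "y_raw")),
       participant_id = unlist(lapply(parts, `[[`, "id")))
}
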