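test_that("repeat averaging is point-wise and checks alignment", {
  x <- sin(seq_len(780) / 50)
  expect_equal(average_prts_repeats(x, x), x)

  noise <- rnorm(780)
  expect_equal(average_prts_repeats(x + noise, x - noise), x)

  expect_error(average_prts_repeats(numeric(780), numeric(779)),
               "lengths differ")
})

test_that("gain spectrum recovers amplitudes exactly at the harmonic bins", {
  sch <- default_schedule()
  h <- stimulated_harmonics(sch)
  n <- sch$period
  t <- seq_len(n) - 1
  input <- sin(2 * pi * 1 * t / n) + 0.5 * sin(2 * pi * 3 * t / n) +
    0.25 * sin(2 * pi * 5 * t / n)

  # static system: gains equal at every harmonic, normalized gains all 1
  sp <- gain_spectrum(input, 2 * input, h)
  expect_equal(sp$gain, rep(2, 3), tolerance = 1e-12)
  expect_equal(sp$normalized_gain, rep(1, 3), tolerance = 1e-12)

  # exact DFT bins: no leakage, amplitudes recovered to 1e-10
  expect_equal(sp$input_amplitude, n / 2 * c(1, 0.5, 0.25), tolerance = 1e-10)

  # mean removal: adding offsets changes nothing
  sp_off <- gain_spectrum(input + 100, 2 * input - 7, h)
  expect_equal(sp_off$gain, sp$gain, tolerance = 1e-12)
})

test_that("even harmonics of the PRTS carry no stimulus", {
  sch <- default_schedule()
  cad <- cadence_signal(sch)
  even_h <- structure(list(fundamental = 1 / sch$period,
                           harmonic_indices = 2L,
                           frequencies = 2 / sch$period),
                      class = "harmonic_set")
  expect_error(gain_spectrum(cad, cad + rnorm(780), even_h),
               "no stimulus at harmonic 2")
})

test_that("first-order gains match the closed form within 1%", {
  sch <- default_schedule()
  h <- stimulated_harmonics(sch)
  cad <- cadence_signal(sch, include_warmup = TRUE)
  resp <- oxydyn:::first_order_response(cad, 30, cad[1])
  keep <- (sch$warmup_duration + 1):(sch$warmup_duration + sch$period)
  sp <- gain_spectrum(cad[keep], resp[keep], h)
  expect_equal(sp$normalized_gain[2], 0.8329, tolerance = 0.01)
  expect_equal(sp$normalized_gain[3], 0.6559, tolerance = 0.01)
})

test_that("MNG follows its closed form and conventions", {
  sch <- default_schedule()
  h <- stimulated_harmonics(sch)

  expect_equal(first_order_mng_closed_form(0, h), 100)
  expect_equal(first_order_mng_closed_form(30, h), 82.96, tolerance = 1e-4)
  expect_equal(first_order_mng_closed_form(30, h, include_first = FALSE),
               74.44, tolerance = 1e-4)
  # tau -> infinity limit: mean of (1, 1/3, 1/5)
  expect_equal(first_order_mng_closed_form(1e9, h), 100 * mean(c(1, 1 / 3, 1 / 5)),
               tolerance = 1e-3)

  # static system measured through the spectrum gives 100%
  t <- seq_len(780) - 1
  input <- sin(2 * pi * t / 780) + 0.3 * sin(2 * pi * 3 * t / 780) +
    0.2 * sin(2 * pi * 5 * t / 780)
  sp <- gain_spectrum(input, 3 * input, h)
  expect_equal(mean_normalized_gain(sp)$mng, 100, tolerance = 1e-10)
  expect_equal(mean_normalized_gain(sp, include_first = FALSE)$harmonics_used,
               c(3, 5))
})

test_that("MNG is strictly decreasing in the time constant (property)", {
  h <- stimulated_harmonics(default_schedule())
  taus <- seq(0, 120, by = 5)
  mngs <- vapply(taus, first_order_mng_closed_form, 0, harmonics = h)
  expect_true(all(diff(mngs) < 0))
})

test_that("normalization removes the static gain (property)", {
  sch <- default_schedule()
  h <- stimulated_harmonics(sch)
  cad <- cadence_signal(sch)
  set.seed(19)
  out <- oxydyn:::first_order_response(cad, 40, cad[1]) + rnorm(780, 0, 2)
  sp1 <- gain_spectrum(cad, out, h)
  for (c_scale in c(0.1, 3, 250)) {
    sp2 <- gain_spectrum(cad, c_scale * out, h)
    expect_equal(sp2$normalized_gain, sp1$normalized_gain, tolerance = 1e-12)
    expect_equal(mean_normalized_gain(sp2)$mng, mean_normalized_gain(sp1)$mng,
                 tolerance = 1e-12)
  }
})

test_that("participant-level MNG matches the oracle on noise-free kinetics", {
  sch <- default_schedule()
  for (tau in c(25, 50)) {
    p <- sim_params(tau_vo2 = tau, noise_sd = noise_free_sd, seed = 2)
    ent <- simulate_participant(p, sch, breath_sampling = FALSE)
    fr <- ent$frame
    res <- participant_mng(fr, fr$channels$VO2, sch)
    # predictions identical to measured VO2: the two MNG values coincide
    expect_equal(res$predicted$mng, res$measured$mng)
    expect_lt(abs(res$measured$mng - ent$truth$mng_true), 2)
  }

  # totality under noise: both MNG values finite
  p_noisy <- sim_params(tau_vo2 = 35, seed = 4)
  ent_n <- simulate_participant(p_noisy, sch)
  fr_n <- ent_n$frame
  res_n <- participant_mng(fr_n, fr_n$channels$VO2 * 0.9, sch)
  expect_true(is.finite(res_n$measured$mng) && is.finite(res_n$predicted$mng))
})
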