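test_that("intrapulse segmentation yields the documented window counts", {
  proto <- fus_protocol(n_pulses = 1L)
  rec <- simulate_pcd(proto, emission_scenario())
  wins <- segment_pulse(rec, 1L, window_layout())
  expect_length(wins, 247L)
  expect_true(all(lengths(wins) == 3125L))

  # degenerate layout: whole pulse as one window
  lay1 <- window_layout(head_cut = 0, window_length = proto$pulse_length,
                        tail_cut = 0)
  expect_length(segment_pulse(rec, 1L, lay1), 1L)

  # 10 ms pulse, 1 ms windows, no cuts -> 10 blocks
  p10 <- fus_protocol(pulse_length = 0.010, n_pulses = 1L)
  r10 <- simulate_pcd(p10, emission_scenario())
  expect_length(segment_pulse(r10, 1L, window_layout(0, 1e-3, 0)), 10L)

  # pulse shorter than head + tail + one window is an error
  expect_error(layout_dims(window_layout(), 500e-6, 15.625e6), "too short")
})

test_that("segmentation conserves samples: head/tail excluded, no overlap", {
  proto <- toy_protocol(n_pulses = 2L)
  rec <- simulate_pcd(proto, emission_scenario())
  rec$samples <- seq_along(rec$samples)  # identify samples by index
  lay <- window_layout()
  dims <- layout_dims(lay, proto$pulse_length, proto$sampling_rate)
  idx <- unlist(segment_pulse(rec, 1L, lay))
  expect_length(idx, dims$n_windows * dims$samples_per_window)
  expect_false(anyDuplicated(idx) > 0)
  expect_equal(min(idx), dims$head_samples + 1)      # head excluded
  spp <- round(proto$pulse_length * proto$sampling_rate)
  expect_lte(max(idx), spp - round(lay$tail_cut * proto$sampling_rate) + 1)
})

test_that("window_dose matches a direct-DFT oracle for pure tones", {
  fs <- 15.625e6; f0 <- 1.5e6; n <- 3125L
  t <- (0:(n - 1)) / fs
  uh <- dose_bands(f0)$uh
  for (A in c(0.3, 1, 2.5)) {
    x <- A * sin(2 * pi * 2.5 * f0 * t + 0.7)
    got <- window_dose(x, fs, uh)
    want <- band_power_oracle(x, fs, uh)
    expect_equal(got, want, tolerance = 1e-10)
    # documented normalization: amplitude A at a band center -> A^2/2
    expect_equal(got, A^2 / 2, tolerance = 0.01)
  }
  # a harmonic tone is invisible to the ultra-harmonic bands
  x2 <- sin(2 * pi * 2 * f0 * t)
  expect_lt(window_dose(x2, fs, uh), 1e-20)
  expect_error(window_dose(x2, fs, 8e6), "Nyquist")
  expect_error(window_dose(numeric(1), fs, uh), "at least 2")
})

test_that("white-noise band power matches its analytic expectation", {
  fs <- 15.625e6; n <- 3125L
  uh <- dose_bands(1.5e6)$uh
  sigma <- 0.4
  doses <- withr::with_seed(11, vapply(seq_len(1000), function(i) {
    window_dose(rnorm(n, sd = sigma), fs, uh)
  }, numeric(1)))
  bins_per_band <- sum((0:(n %/% 2)) * fs / n >= uh[1] - 25e3 &
                         (0:(n %/% 2)) * fs / n < uh[1] + 25e3)
  expected <- 3 * bins_per_band * 2 * sigma^2 / n
  expect_equal(mean(doses), expected, tolerance = 0.05)
})

test_that("doses of spectrally disjoint signals add within FFT leakage", {
  fs <- 15.625e6; f0 <- 1.5e6; n <- 3125L
  t <- (0:(n - 1)) / fs
  bands <- c(dose_bands(f0)$uh, dose_bands(f0)$h)
  a <- 0.8 * sin(2 * pi * 1.5 * f0 * t)
  b <- 0.5 * sin(2 * pi * 3 * f0 * t)
  expect_equal(window_dose(a + b, fs, bands),
               window_dose(a, fs, bands) + window_dose(b, fs, bands),
               tolerance = 0.01)
})

test_that("compute_doses fills pulse-by-window matrices of both dose kinds", {
  proto <- toy_protocol(n_pulses = 3L)
  lay <- window_layout()
  dims <- layout_dims(lay, proto$pulse_length, proto$sampling_rate)

  silent <- compute_doses(simulate_pcd(proto, emission_scenario()), lay)
  expect_equal(dim(silent$iud), c(3L, dims$n_windows))
  expect_true(all(silent$iud == 0) && all(silent$ihd == 0))

  # harmonic-only emissions: IHD far above the noise floor, IUD at it
  sc <- emission_scenario(harmonic_amps = c(0.5, 0.3, 0.2),
                          background_noise_sd = 0.01, seed = 5)
  d <- compute_doses(simulate_pcd(proto, sc, lay), lay)
  d <- estimate_noise(d)
  expect_lt(max(d$iud) / d$noise_level, 6)
  expect_gt(min(d$ihd) / d$noise_level, 100)
})

test_that("noise estimation is robust to sparse high-dose windows", {
  d <- dose_stub(matrix(7, 4, 50))
  expect_equal(estimate_noise(d)$noise_level, 7)

  # 95% of windows at noise n, 5% bursts at 100 n
  n0 <- 2e-6
  iud <- withr::with_seed(3, {
    m <- matrix(n0 * (1 + 0.05 * rnorm(60 * 247)), 60, 247)
    burst <- sample(length(m), round(0.05 * length(m)))
    m[burst] <- 100 * n0
    m
  })
  est <- estimate_noise(dose_stub(iud))$noise_level
  expect_equal(est, n0, tolerance = 0.05)

  expect_error(estimate_noise(dose_stub(iud), q = 0), "q must")
  expect_error(estimate_noise(dose_stub(iud), method = "reference_pulses"),
               "non-empty")
  expect_equal(estimate_noise(dose_stub(iud), method = "reference_pulses",
                              reference_pulses = 1:2)$noise_level,
               mean(iud[1:2, ]))
})

test_that("event flagging and run counting match a brute-force scanner", {
  # no window above threshold
  d <- flag_events(dose_stub(matrix(1, 5, 40)), 6)
  expect_equal(d$pct_inertial, 0)
  expect_equal(d$pct_consecutive, 0)

  # isolated flagged windows are not consecutive events
  iud <- matrix(1, 5, 40); iud[, 10] <- 100
  d <- flag_events(dose_stub(iud), 6, run_min = 2L)
  expect_gt(d$pct_inertial, 0)
  expect_equal(d$pct_consecutive, 0)

  # an 11-window run in one pulse of a 60 x 247 series
  iud <- matrix(1, 60, 247); iud[7, 31:41] <- 100
  d <- flag_events(dose_stub(iud), 6)
  expect_equal(d$pct_inertial, 11 / 14820 * 100)
  expect_equal(d$pct_consecutive, d$pct_inertial)

  # property: agreement with the exhaustive run scanner on random matrices
  withr::with_seed(21, {
    for (i in 1:25) {
      flags <- matrix(runif(12 * 30) < runif(1, 0.05, 0.6), 12, 30)
      rm <- sample(2:4, 1)
      d <- flag_events(dose_stub(ifelse(flags, 100, 1)), 6, run_min = rm)
      want <- run_stats_oracle(flags, rm)
      expect_identical(d$event_flags, flags)
      expect_equal(d$pct_inertial, want$pct_inertial)
      expect_equal(d$pct_consecutive, want$pct_consecutive)
    }
  })
  expect_error(flag_events(dose_stub(iud), -1), "threshold")
  expect_error(flag_events(dose_stub(iud, noise_level = NA)), "noise_level")
})

test_that("verdicts follow the soft/mild/hard decision rule", {
  quiet <- flag_events(dose_stub(matrix(1, 10, 100)), 6)
  expect_equal(classify(quiet)$label, "soft")

  # every window of one pulse flagged: sustained suprathreshold -> hard
  iud <- matrix(1, 10, 100); iud[4, ] <- 100
  expect_equal(classify(flag_events(dose_stub(iud), 6))$label, "hard")
  expect_true(classify(flag_events(dose_stub(iud), 6))$any_pulse_mean_above)

  # the mild/hard extreme case (6.3% total, 6% consecutive): hard by the
  # default consecutive cutoff of 3%
  # events just above threshold so no pulse mean is suprathreshold
  iud <- matrix(1, 10, 1000)
  iud[1, 1:60] <- 7            # one 60-window run
  iud[2, seq(2, 8, 2)] <- 7    # isolated singles
  d <- flag_events(dose_stub(iud), 6)
  expect_equal(d$pct_consecutive, 6/ 10, tolerance = 1e-9) # of 10k windows
  v <- classify(d)
  expect_false(v$any_pulse_mean_above)
  # rescale to per-animal percentages as in the decision rule
  d$pct_inertial <- 6.3; d$pct_consecutive <- 6.0
  expect_equal(classify(d)$label, "hard")
  d$pct_consecutive <- 2.0
  expect_equal(classify(d)$label, "mild")
  d$pct_inertial <- 1.4; d$pct_consecutive <- 0.3
  expect_equal(classify(d)$label, "soft")
  # strict soft mode requires zero events
  expect_equal(classify(d, soft_mode = "no_events")$label, "mild")
  d$pct_inertial <- 0; d$pct_consecutive <- 0
  expect_equal(classify(d, soft_mode = "no_events")$label, "soft")
})

test_that("verdicts are monotone in run length and scale invariant", {
  severity <- c(soft = 1L, mild = 2L, hard = 3L)
  labels <- integer(0)
  for (run_len in c(0, 1, 3, 8, 30, 100)) {
    iud <- matrix(1, 10, 100)
    if (run_len > 0) iud[3, seq_len(run_len)] <- 100
    v <- classify(flag_events(dose_stub(iud), 6))
    labels <- c(labels, severity[[v$label]])
  }
  expect_true(all(diff(labels) >= 0))

  # multiplying the whole recording by a constant changes nothing
  proto <- toy_protocol(n_pulses = 4L)
  sc <- make_scenario("mild", proto, seed = 17)
  rec <- simulate_pcd(proto, sc)
  base <- analyse_cavitation(rec)
  rec$samples <- rec$samples * 7.3
  scaled <- analyse_cavitation(rec)
  expect_equal(scaled$verdict$pct_inertial, base$verdict$pct_inertial)
  expect_equal(scaled$verdict$pct_consecutive, base$verdict$pct_consecutive)
  expect_identical(scaled$verdict$label, base$verdict$label)
})

test_that("the consecutive-vs-total event relation is fit by least squares", {
  fit <- fit_event_relation(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  expect_warning(f0 <- fit_event_relation(c(1, 2, 3), c(0, 0, 0)),
                 "zero variance")
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  expect_error(fit_event_relation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(fit_event_relation(1:2, 1:2), "at least 3")

  withr::with_seed(9, {
    total <- runif(20, 0, 8)
    consec <- 0.9 * total + rnorm(20, sd = 0.3)
    fit <- fit_event_relation(total, consec)
    se <- sqrt(sum(stats::lm(consec ~ total)$residuals^2 / 18) /
                 sum((total - mean(total))^2))
    expect_lt(abs(fit$slope - 0.9), 3 * se)
    expect_gt(fit$r_squared, 0.8)
  })
})
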