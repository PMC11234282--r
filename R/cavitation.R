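#' Segment one pulse into intrapulse analysis windows
#'
#' Applies the head cut (transducer switching transients), splits the
#' remainder into contiguous windows, and discards the tail. With the default
#' layout a 50 ms pulse at 15.625 MHz yields 247 windows of 3125 samples;
#' no sample is analysed twice and head/tail samples are never analysed.
#'
#' @param recording A `pcd_recording`.
#' @param pulse_index 1-based pulse index.
#' @param layout A [window_layout()].
#' @return List of numeric vectors, one per window.
#' @export
segment_pulse <- function(recording, pulse_index, layout = window_layout()) {
  stopifnot(inherits(recording, "pcd_recording"),
            pulse_index >= 1, pulse_index <= recording$n_pulses)
  dims <- layout_dims(layout, recording$pulse_length, recording$sampling_rate)
  start <- recording$pulse_starts[pulse_index] + dims$head_samples
  lapply(seq_len(dims$n_windows), function(w) {
    i0 <- start + (w - 1L) * dims$samples_per_window
    recording$samples[i0:(i0 + dims$samples_per_window - 1L)]
  })
}

#' Band power of one analysis window
#'
#' Discrete Fourier transform of the window, one-sided power spectrum
#' normalised so that a unit-amplitude sinusoid at a bin center carries power
#' 1/2 (i.e. A^2/2 for amplitude A), summed over `[f - bandwidth/2,
#' f + bandwidth/2)` around each listed band center. Bin inclusion is
#' closed-open on the discrete frequency grid, so the lower band edge is
#' included and the upper excluded. No taper is applied by default; a Hann
#' taper (with coherent-gain compensation) is available.
#'
#' @param window Numeric vector of samples.
#' @param sampling_rate Hz.
#' @param bands Band center frequencies, Hz.
#' @param bandwidth Full integration bandwidth per band, Hz (default 50 kHz).
#' @param taper `"none"` (default) or `"hann"`.
#' @return Scalar band power (a.u.^2).
#' @export
window_dose <- function(window, sampling_rate, bands, bandwidth = 50e3,
                        taper = c("none", "hann")) {
  taper <- match.arg(taper)
  n <- length(window)
  if (n < 2) stop("window must contain at least 2 samples")
  if (any(bands + bandwidth / 2 > sampling_rate / 2))
    stop("band extends above Nyquist")
  if (taper == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    window <- window * h / mean(h)
  }
  X <- stats::fft(window)
  half <- seq_len(floor(n / 2) + 1L)
  p <- 2 * Mod(X[half])^2 / n^2     # one-sided; sinusoid amplitude A -> A^2/2
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  f <- (half - 1) * sampling_rate / n
  total <- 0
  for (fc in bands) {
    sel <- f >= fc - bandwidth / 2 & f < fc + bandwidth / 2
    total <- total + sum(p[sel])
  }
  total
}

#' Compute intrapulse ultra-harmonic and harmonic dose matrices
#'
#' Runs [window_dose()] on every analysis window of every pulse with the
#' ultra-harmonic band set (1.5, 2.5, 3.5 f0; IUD) and the harmonic band set
#' (2, 3, 4 f0; IHD), each integrated over a 50 kHz bandwidth.
#'
#' @param recording A `pcd_recording`.
#' @param layout A [window_layout()].
#' @param bandwidth Hz.
#' @param taper Passed to [window_dose()].
#' @return A `dose_series`: list with `iud` and `ihd` matrices
#'   (pulse x window), band definitions, and placeholders for the noise
#'   reference and event flags filled by [estimate_noise()] and
#'   [flag_events()].
#' @export
compute_doses <- function(recording, layout = window_layout(),
                          bandwidth = 50e3, taper = "none") {
  bands <- dose_bands(recording$f0)
  dims <- layout_dims(layout, recording$pulse_length, recording$sampling_rate)
  np <- recording$n_pulses
  iud <- matrix(0, np, dims$n_windows)
  ihd <- matrix(0, np, dims$n_windows)
  for (p in seq_len(np)) {
    wins <- segment_pulse(recording, p, layout)
    for (w in seq_along(wins)) {
      iud[p, w] <- window_dose(wins[[w]], recording$sampling_rate,
                               bands$uh, bandwidth, taper)
      ihd[p, w] <- window_dose(wins[[w]], recording$sampling_rate,
                               bands$h, bandwidth, taper)
    }
  }
  structure(list(iud = iud, ihd = ihd,
                 bands_uh = bands$uh, bands_h = bands$h,
                 bandwidth = bandwidth, taper = taper,
                 noise_level = NA_real_, threshold_multiplier = NA_real_,
                 event_flags = NULL),
            class = "dose_series")
}

#' Estimate the noise reference from the dose series itself
#'
#' The method needs no pre-injection baseline: the noise floor is referenced
#' from the recording. `lower_quantile` takes the median of the lowest `q`
#' fraction of all IUD values (robust to sparse bursts); `reference_pulses`
#' averages the IUD over user-designated pulses.
#'
#' @param doses A `dose_series`.
#' @param method `"lower_quantile"` or `"reference_pulses"`.
#' @param q Fraction of lowest IUD values used (default 0.25).
#' @param reference_pulses Integer pulse indices for `"reference_pulses"`.
#' @return The `dose_series` with `noise_level` set.
#' @export
estimate_noise <- function(doses, method = c("lower_quantile", "reference_pulses"),
                           q = 0.25, reference_pulses = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(doses, "dose_series"), length(doses$iud) > 0)
  if (method == "lower_quantile") {
    if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
    v <- sort(as.vector(doses$iud))
    k <- max(1L, floor(length(v) * q))
    doses$noise_level <- stats::median(v[seq_len(k)])
  } else {
    if (is.null(reference_pulses) || length(reference_pulses) == 0)
      stop("reference_pulses must be a non-empty set of pulse indices")
    doses$noise_level <- mean(doses$iud[reference_pulses, , drop = FALSE])
  }
  doses
}

#' Flag inertial cavitation events and count consecutive runs
#'
#' A window is inertial when its relative signal IUD / noise_level exceeds
#' the threshold multiplier. Consecutive events are counted as runs of at
#' least `run_min` flagged windows within a pulse (runs never span pulse
#' boundaries). Both counts are expressed as percentages of all analysed
#' windows.
#'
#' @param doses A `dose_series` with `noise_level` set.
#' @param threshold_multiplier Relative-signal threshold (default 6).
#' @param run_min Minimum run length counted as consecutive (default 2).
#' @return The `dose_series` with `event_flags`, `threshold_multiplier`,
#'   `run_min`, `pct_inertial`, `pct_consecutive` and `pulse_mean_relative`
#'   (per-pulse mean of IUD / noise_level) filled in.
#' @export
flag_events <- function(doses, threshold_multiplier = 6, run_min = 2L) {
  stopifnot(inherits(doses, "dose_series"))
  if (!is.finite(doses$noise_level) || doses$noise_level <= 0)
    stop("noise_level must be set (estimate_noise) and > 0")
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be > 0")
  rel <- doses$iud / doses$noise_level
  flags <- rel > threshold_multiplier
  n_total <- length(flags)
  in_run <- matrix(FALSE, nrow(flags), ncol(flags))
  for (p in seq_len(nrow(flags))) {
    r <- rle(flags[p, ])
    keep <- r$values & r$lengths >= run_min
    in_run[p, ] <- rep(keep, r$lengths)
  }
  doses$event_flags <- flags
  doses$threshold_multiplier <- threshold_multiplier
  doses$run_min <- as.integer(run_min)
  doses$pct_inertial <- 100 * sum(flags) / n_total
  doses$pct_consecutive <- 100 * sum(in_run) / n_total
  doses$pulse_mean_relative <- rowMeans(rel)
  doses
}

#' Classify a sonication as soft, mild or hard
#'
#' Hard: some pulse's mean relative signal stays above the inertial threshold
#' (the sustained-suprathreshold signature) or the consecutive-event fraction
#' exceeds `hard_cutoff`. Otherwise soft if both event fractions stay within
#' the soft cutoffs (`soft_mode = "maxima"`), or if no window at all was
#' flagged (`soft_mode = "no_events"`); otherwise mild.
#'
#' @param doses A `dose_series` after [flag_events()], or a list carrying
#'   `pct_inertial`, `pct_consecutive`, `pulse_mean_relative`,
#'   `threshold_multiplier`.
#' @param cutoffs List with `soft_inertial` (default 1.4, \%), `soft_consecutive`
#'   (default 0.3, \%), `hard` (default 3, \%).
#' @param soft_mode `"maxima"` (default) or `"no_events"`.
#' @return A `cavitation_verdict`: list with `label`, `pct_inertial`,
#'   `pct_consecutive`, `any_pulse_mean_above`, and the cutoffs used.
#' @export
classify <- function(doses,
                     cutoffs = list(soft_inertial = 1.4, soft_consecutive = 0.3,
                                    hard = 3),
                     soft_mode = c("maxima", "no_events")) {
  soft_mode <- match.arg(soft_mode)
  stopifnot(is.finite(doses$pct_inertial), is.finite(doses$pct_consecutive))
  any_above <- any(doses$pulse_mean_relative > doses$threshold_multiplier)
  label <- if (any_above || doses$pct_consecutive > cutoffs$hard) {
    "hard"
  } else if (soft_mode == "no_events" && doses$pct_inertial == 0) {
    "soft"
  } else if (soft_mode == "maxima" &&
             doses$pct_inertial <= cutoffs$soft_inertial &&
             doses$pct_consecutive <= cutoffs$soft_consecutive) {
    "soft"
  } else {
    "mild"
  }
  structure(list(label = label,
                 pct_inertial = doses$pct_inertial,
                 pct_consecutive = doses$pct_consecutive,
                 any_pulse_mean_above = any_above,
                 cutoffs = cutoffs, soft_mode = soft_mode,
                 threshold_multiplier = doses$threshold_multiplier),
            class = "cavitation_verdict")
}

#' Linear relation between consecutive and total inertial events
#'
#' Ordinary least squares of per-subject consecutive-event percentage on
#' total inertial-event percentage, with R^2. With zero variance in the
#' response the fit is degenerate and R^2 is reported as 0 with a warning.
#'
#' @param pct_inertial Numeric vector (one value per subject).
#' @param pct_consecutive Numeric vector, same length.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_event_relation <- function(pct_inertial, pct_consecutive) {
  stopifnot(length(pct_inertial) == length(pct_consecutive))
  if (length(pct_inertial) < 3) stop("need at least 3 subjects")
  if (stats::var(pct_inertial) == 0) stop("zero variance in predictor")
  fit <- stats::lm(pct_consecutive ~ pct_inertial)
  tss <- sum((pct_consecutive - mean(pct_consecutive))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  if (stats::var(pct_consecutive) == 0) {
    warning("response has zero variance; R^2 reported as 0")
    r2 <- 0
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(pct_inertial))
}

#' Full cavitation analysis of one recording
#'
#' Convenience wrapper: doses, noise reference, event flags, verdict.
#'
#' @inheritParams compute_doses
#' @inheritParams flag_events
#' @inheritParams classify
#' @param noise_method Passed to [estimate_noise()].
#' @return List with `doses` (a `dose_series`) and `verdict`.
#' @export
analyse_cavitation <- function(recording, layout = window_layout(),
                               bandwidth = 50e3, threshold_multiplier = 6,
                               run_min = 2L, noise_method = "lower_quantile",
                               cutoffs = list(soft_inertial = 1.4,
                                              soft_consecutive = 0.3, hard = 3),
                               soft_mode = "maxima") {
  d <- compute_doses(recording, layout, bandwidth)
  d <- estimate_noise(d, noise_method)
  d <- flag_events(d, threshold_multiplier, run_min)
  list(doses = d, verdict = classify(d, cutoffs, soft_mode))
}
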