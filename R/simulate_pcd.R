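#' Simulate a passive cavitation detector recording
#'
#' Forward model for the receive-only cavitation monitor: each pulse is a sum
#' of sinusoids at the configured harmonic (2, 3, 4 f0) and ultra-harmonic
#' (1.5, 2.5, 3.5 f0) frequencies, white Gaussian background noise, optional
#' band-limited (0.3-6 MHz) broadband segments confined to designated
#' analysis windows, and an optional exponentially decaying switching
#' transient in the first 200 microseconds of each pulse. No inter-pulse
#' dead time is stored: pulses are concatenated and indexed by
#' `pulse_starts`.
#'
#' @param protocol A [fus_protocol()].
#' @param scenario An [emission_scenario()].
#' @param layout A [window_layout()] used only to place broadband bursts on
#'   the analysis-window grid; defaults to the standard layout.
#' @return A `pcd_recording`: list with `samples` (numeric vector, a.u.),
#'   `sampling_rate`, `f0`, `pulse_starts` (1-based sample indices),
#'   `pulse_length`, `n_pulses`.
#' @export
simulate_pcd <- function(protocol, scenario, layout = window_layout()) {
  stopifnot(inherits(protocol, "fus_protocol"),
            inherits(scenario, "emission_scenario"))
  fs <- protocol$sampling_rate
  f0 <- protocol$center_frequency
  spp <- as.integer(round(protocol$pulse_length * fs))
  np <- protocol$n_pulses
  dims <- layout_dims(layout, protocol$pulse_length, fs)

  freqs <- c(dose_bands(f0)$uh, dose_bands(f0)$h)
  amps <- c(scenario$ultraharmonic_amps, scenario$harmonic_amps)
  if (any(freqs[amps > 0] >= fs / 2))
    stop("configured emission frequency at or above Nyquist")
  for (b in scenario$broadband_bursts) {
    if (b$pulse < 1 || b$pulse > np)
      stop("broadband burst pulse index out of range")
    if (any(b$windows < 1) || any(b$windows > dims$n_windows))
      stop("broadband burst window range outside the analysis windows")
  }

  t_pulse <- (seq_len(spp) - 1) / fs
  tone <- rep(0, spp)
  for (i in seq_along(freqs))
    if (amps[i] > 0) tone <- tone + amps[i] * sin(2 * pi * freqs[i] * t_pulse)
  if (scenario$transient_amp > 0) {
    # decaying chirp standing in for transducer switching, confined to the
    # first 200 us of each pulse (the segment the head cut discards)
    tau <- 50e-6
    tone <- tone + scenario$transient_amp * exp(-t_pulse / tau) *
      (t_pulse < 200e-6) *
      sin(2 * pi * (0.2e6 + 4e6 * t_pulse / 200e-6) * t_pulse)
  }

  samples <- withr::with_seed(scenario$seed, {
    x <- rep(tone, np)
    if (scenario$background_noise_sd > 0)
      x <- x + stats::rnorm(spp * np, sd = scenario$background_noise_sd)
    for (b in scenario$broadband_bursts) {
      for (w in b$windows) {
        i0 <- (b$pulse - 1L) * spp + dims$head_samples +
          (w - 1L) * dims$samples_per_window
        idx <- (i0 + 1L):(i0 + dims$samples_per_window)
        x[idx] <- x[idx] + bandlimited_noise(dims$samples_per_window, fs,
                                             0.3e6, 6e6, b$sd)
      }
    }
    x
  })

  structure(list(samples = samples,
                 sampling_rate = fs,
                 f0 = f0,
                 pulse_starts = as.integer((seq_len(np) - 1L) * spp + 1L),
                 pulse_length = protocol$pulse_length,
                 n_pulses = np),
            class = "pcd_recording")
}

# White Gaussian noise restricted to [f_lo, f_hi] by zeroing out-of-band FFT
# coefficients; sd is the in-band time-domain standard deviation.
bandlimited_noise <- function(n, fs, f_lo, f_hi, sd) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency magnitude
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) rep(0, n) else y * (sd / s)
}

#' Write / read a PCD recording as raw float32 with a JSON sidecar
#'
#' The sample stream is stored little-endian float32; acquisition metadata
#' (sampling rate, f0, pulse markers, pulse length) go to `<path>.json`.
#'
#' @param rec A `pcd_recording`.
#' @param path Output path for the binary stream (sidecar at `<path>.json`).
#' @return `write_pcd` returns `path` invisibly; `read_pcd` returns a
#'   `pcd_recording`.
#' @export
write_pcd <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  meta <- rec[c("sampling_rate", "f0", "pulse_starts", "pulse_length",
                "n_pulses")]
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pcd
#' @param sidecar Path to the JSON sidecar; defaults to `<path>.json`.
#' @export
read_pcd <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- file.info(path)$size / 4L
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  structure(list(samples = samples,
                 sampling_rate = meta$sampling_rate,
                 f0 = meta$f0,
                 pulse_starts = as.integer(meta$pulse_starts),
                 pulse_length = meta$pulse_length,
                 n_pulses = as.integer(meta$n_pulses)),
            class = "pcd_recording")
}
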