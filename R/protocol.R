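#' FUS exposure protocol
#'
#' Describes the pulsed focused-ultrasound exposure used for blood-brain
#' barrier opening: 50 ms bursts at a 1 Hz pulse repetition frequency
#' (duty cycle 5\%) for 60 s, monitored by a passive cavitation detector
#' digitised at 15.625 MHz. The sampling rate must resolve the 4th harmonic
#' of the transmit frequency, since harmonic doses are integrated up to
#' 4 f0.
#'
#' @param center_frequency Transmit center frequency f0 in Hz.
#' @param pulse_length Burst duration in seconds.
#' @param prf Pulse repetition frequency in Hz.
#' @param n_pulses Number of bursts in the sonication.
#' @param target_pnp Target in-situ peak negative pressure in MPa.
#' @param sampling_rate PCD digitisation rate in Hz.
#' @return A `fus_protocol` object (list) with a derived `duty_cycle`.
#' @examples
#' p <- fus_protocol()
#' p$duty_cycle  # 0.05
#' @export
fus_protocol <- function(center_frequency = 1.5e6,
                         pulse_length = 0.050,
                         prf = 1.0,
                         n_pulses = 60,
                         target_pnp = 0.6,
                         sampling_rate = 15.625e6) {
  stopifnot(center_frequency > 0, pulse_length > 0, prf > 0,
            n_pulses >= 1, sampling_rate > 0)
  duty_cycle <- pulse_length * prf
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty cycle must lie in (0, 1]; got ", duty_cycle)
  if (sampling_rate <= 2 * 4 * center_frequency)
    stop("sampling_rate must exceed twice the 4th harmonic (",
         2 * 4 * center_frequency, " Hz) to satisfy Nyquist")
  structure(list(
    center_frequency = center_frequency,
    pulse_length = pulse_length,
    prf = prf,
    n_pulses = as.integer(n_pulses),
    target_pnp = target_pnp,
    sampling_rate = sampling_rate,
    duty_cycle = duty_cycle
  ), class = "fus_protocol")
}

#' Intrapulse analysis window layout
#'
#' Each burst is analysed in contiguous short windows after discarding a head
#' segment (non-linear switching transients of the transducer) and a tail
#' segment (end-of-pulse distortions). With the defaults on a 50 ms pulse the
#' layout yields 247 windows of 200 microseconds.
#'
#' @param head_cut Seconds discarded at the start of each pulse.
#' @param window_length Analysis window duration in seconds.
#' @param tail_cut Seconds discarded at the end of each pulse.
#' @return A `window_layout` object.
#' @export
window_layout <- function(head_cut = 200e-6,
                          window_length = 200e-6,
                          tail_cut = 400e-6) {
  stopifnot(head_cut >= 0, tail_cut >= 0, window_length > 0)
  structure(list(head_cut = head_cut,
                 window_length = window_length,
                 tail_cut = tail_cut),
            class = "window_layout")
}

#' Resolve a window layout against a pulse
#'
#' @param layout A [window_layout()].
#' @param pulse_length Pulse duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @return List with `n_windows`, `samples_per_window`, `head_samples`.
#' @export
layout_dims <- function(layout, pulse_length, sampling_rate) {
  analysable <- pulse_length - layout$head_cut - layout$tail_cut
  if (analysable < layout$window_length)
    stop("pulse too short: ", pulse_length, " s leaves no analysis window ",
         "after head (", layout$head_cut, " s) and tail (", layout$tail_cut,
         " s) cuts")
  # floor() on the exact ratio, guarded against representation error
  n_windows <- floor(analysable / layout$window_length + 1e-9)
  list(n_windows = as.integer(n_windows),
       samples_per_window = as.integer(round(layout$window_length * sampling_rate)),
       head_samples = as.integer(round(layout$head_cut * sampling_rate)))
}

#' Acoustic emission scenario for the PCD simulator
#'
#' Encodes which spectral components a simulated sonication contains: stable
#' cavitation appears as harmonics of f0 (2, 3, 4 f0), the onset of inertial
#' cavitation as ultra-harmonics (1.5, 2.5, 3.5 f0), and violent bubble
#' collapse as broadband bursts confined to designated analysis windows.
#'
#' @param harmonic_amps Amplitudes (a.u.) at 2, 3, 4 f0.
#' @param ultraharmonic_amps Amplitudes (a.u.) at 1.5, 2.5, 3.5 f0.
#' @param broadband_bursts List of lists with fields `pulse` (1-based pulse
#'   index), `windows` (integer vector of 1-based window indices) and `sd`
#'   (spectral amplitude, a.u.) marking windows that carry band-limited
#'   broadband noise.
#' @param background_noise_sd Standard deviation of the white Gaussian
#'   background (a.u.).
#' @param transient_amp Amplitude of the decaying switching transient
#'   simulated in the first 200 microseconds of each pulse (exercises the
#'   head cut); 0 disables it.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical recordings.
#' @export
emission_scenario <- function(harmonic_amps = c(0, 0, 0),
                              ultraharmonic_amps = c(0, 0, 0),
                              broadband_bursts = list(),
                              background_noise_sd = 0,
                              transient_amp = 0,
                              seed = 1L) {
  stopifnot(length(harmonic_amps) == 3, length(ultraharmonic_amps) == 3,
            all(harmonic_amps >= 0), all(ultraharmonic_amps >= 0),
            background_noise_sd >= 0, transient_amp >= 0)
  for (b in broadband_bursts) {
    stopifnot(is.list(b), !is.null(b$pulse), !is.null(b$windows), !is.null(b$sd))
    if (b$sd < 0) stop("broadband burst spectral density must be >= 0")
  }
  structure(list(harmonic_amps = harmonic_amps,
                 ultraharmonic_amps = ultraharmonic_amps,
                 broadband_bursts = broadband_bursts,
                 background_noise_sd = background_noise_sd,
                 transient_amp = transient_amp,
                 seed = as.integer(seed)),
            class = "emission_scenario")
}

#' Harmonic and ultra-harmonic band centers
#'
#' @param f0 Center frequency in Hz.
#' @return List with `uh` (1.5, 2.5, 3.5 f0) and `h` (2, 3, 4 f0).
#' @export
dose_bands <- function(f0) {
  list(uh = c(1.5, 2.5, 3.5) * f0, h = c(2, 3, 4) * f0)
}
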