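# Shared fixtures: desk-scale protocols and independent oracles.

toy_protocol <- function(n_pulses = 4L, pulse_length = 0.005) {
  fus_protocol(pulse_length = pulse_length, n_pulses = n_pulses)
}

# Direct-DFT band power oracle: evaluates the DFT only at the requested bins
# by explicit summation (independent of the fft-based implementation path).
band_power_oracle <- function(x, fs, bands, bandwidth = 50e3) {
  n <- length(x)
  k_all <- 0:(floor(n / 2))
  f <- k_all * fs / n
  total <- 0
  for (fc in bands) {
    ks <- k_all[f >= fc - bandwidth / 2 & f < fc + bandwidth / 2]
    for (k in ks) {
      w <- exp(-2i * pi * k * (0:(n - 1)) / n)
      Xk <- sum(x * w)
      p <- 2 * Mod(Xk)^2 / n^2
      if (k == 0 || (n %% 2 == 0 && k == n / 2)) p <- p / 2
      total <- total + p
    }
  }
  total
}

# Brute-force run statistics on a boolean matrix: percentage of windows
# flagged and percentage lying in within-row runs of length >= run_min.
run_stats_oracle <- function(flags, run_min) {
  n_total <- length(flags)
  in_run <- 0L
  for (p in seq_len(nrow(flags))) {
    row <- flags[p, ]
    i <- 1L
    while (i <= length(row)) {
      if (row[i]) {
        j <- i
        while (j < length(row) && row[j + 1L]) j <- j + 1L
        if (j - i + 1L >= run_min) in_run <- in_run + (j - i + 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  list(pct_inertial = 100 * sum(flags) / n_total,
       pct_consecutive = 100 * in_run / n_total)
}

# Exhaustive 2^n enumeration oracle for the two-tailed signed-rank p-value,
# using the same zero-drop / mid-rank conventions.
wilcoxon_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force single-linkage site counter: connected components of the
# graph joining points closer than the radius.
rbc_sites_oracle <- function(pts, radius, min_count) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  D <- as.matrix(stats::dist(pts))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (D[i, j] <= radius && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sum(table(comp) >= min_count)
}

# Dose series stub with prescribed IUD values (for flag/classify tests).
dose_stub <- function(iud, noise_level = 1, ihd = iud * 0) {
  structure(list(iud = iud, ihd = ihd,
                 bands_uh = c(2.25e6, 3.75e6, 5.25e6),
                 bands_h = c(3e6, 4.5e6, 6e6),
                 bandwidth = 50e3, taper = "none",
                 noise_level = noise_level, threshold_multiplier = NA_real_,
                 event_flags = NULL),
            class = "dose_series")
}
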