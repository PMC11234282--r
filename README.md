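# sonoperm

Quantitative analysis of microbubble-assisted focused-ultrasound (FUS)
blood–brain-barrier (BBB) opening experiments, as an R package.

Opening the BBB with low-intensity pulsed FUS and circulating microbubbles
is a route for drug delivery to the brain, but its safety hinges on keeping
the bubbles oscillating stably (harmonic emissions) rather than collapsing
inertially (ultra-harmonic, then broadband emissions). `sonoperm`
implements the full measurement chain used to monitor and evaluate such
procedures:

- **Cavitation dose analysis.** Each 50 ms burst recorded by a passive
  cavitation detector (sampled at 15.625 MHz) is cut into 200 µs analysis
  windows (discarding 200 µs of transducer switching transients at the head
  and 400 µs of distortions at the tail — 247 windows per burst at the
  standard settings). Per window, the intrapulse ultra-harmonic dose (IUD)
  and intrapulse harmonic dose (IHD) are the one-sided FFT band powers
  summed over {1.5, 2.5, 3.5}·f₀ and {2, 3, 4}·f₀ with a 50 kHz bandwidth.
  Windows whose relative signal IUD/noise exceeds a threshold multiplier
  (default 6) are inertial events; runs of ≥ 2 within a pulse are
  consecutive events, and each sonication is classified **soft / mild /
  hard** from the event fractions and the presence of a sustained
  suprathreshold pulse. The noise reference comes from the recording itself
  (lower-quantile of the IUD field), so no pre-injection baseline is needed.
- **Quantitative MRI.** Per-voxel parametric maps with their standard
  models: T1 by magnitude inversion-recovery fitting |M₀(1 − 2κ e^(−TI/T1))|;
  cerebral blood flow (CBF, mL/100g/min) by the single-compartment pCASL
  model CBF = 6000·λ·ΔM·e^(PLD/T1) / (2·α·T1·M₀·(1 − e^(−τ/T1)));
  blood volume fraction BVf[%] = 100·(3/4π)·ΔR2\*/(γ·Δχ·B₀) from pre/post-USPIO
  multi-gradient-echo decays; apparent diffusion coefficient (ADC) as the
  diffusion-tensor trace/3 (direction-average fallback); gadolinium
  enhancement 100·(post − pre)/pre with automated k·SD delineation of the
  opened volume. Pressure derating (exp(−α·f·depth), α = 5 Np/m/MHz) and
  the mechanical index PNP/√f are included.
- **Fluorescence histology.** Marker area fraction and mean intensity
  (Otsu or fixed thresholds), vessel morphometry (skeleton centerlines,
  path length, diameter from the distance transform, tortuosity =
  path/chord), and red-blood-cell extravasation sites (single-linkage
  clusters of ≥ 5 cells).
- **Statistics.** Paired ipsilateral/contralateral ROI summaries, percent
  reductions 100·(1 − ipsi/contra), and an exact two-tailed Wilcoxon
  signed-rank test (full-enumeration null for n ≤ 25).
- **Synthetic data.** Seeded simulators for PCD recordings (harmonics,
  ultra-harmonics, band-limited broadband bursts, switching transients),
  MR acquisitions (exact forward models of each quantification, Rician
  noise) and fluorescence images, each with known ground truth — every
  stage is testable end to end without scanner data.

## Worked example

```r
library(sonoperm)

# --- cavitation: simulate a mild sonication and classify it -------------
proto <- fus_protocol(pulse_length = 0.005, n_pulses = 10)  # desk scale
scen  <- make_scenario("mild", proto, seed = 42)
rec   <- simulate_pcd(proto, scen)
res   <- analyse_cavitation(rec)
res$verdict
#> verdict: mild
#> inertial windows: 2.27%
#> consecutive windows: 0.91%
#> noise level: 1.54e-06 a.u.^2

# --- MRI: quantify a noisy phantom session ------------------------------
ph    <- make_phantom(dim = c(16, 16, 2))   # truth: CBF 93.57 / 42.24,
masks <- phantom_masks(ph)                  # BVf 3.9 / 3.4, 18.66% core
s     <- quantify_phantom_session(ph, noise_sd = 0.5, seed = 7)
cbf_i <- extract_roi(s$maps$cbf, masks$ipsi)$mean    # 42.54
cbf_c <- extract_roi(s$maps$cbf, masks$contra)$mean  # 94.03
relative_change(cbf_i, cbf_c)$rounded                # 55 (% reduction)
extract_roi(s$maps$enhancement, masks$core)$mean     # 18.85 (%)

# --- statistics: exact paired Wilcoxon ----------------------------------
wilcoxon_exact(c(40.1, 45.3, 38.2, 50.4, 42.9, 44.0),
               c(90.2, 95.1, 88.4, 100.3, 92.5, 85.8))$p_value
#> 0.03125
```

The verdict says 2.27% of the analysed windows crossed the inertial
threshold and 0.91% lay in consecutive runs — above the soft limits
(1.4% / 0.3%) but below the hard consecutive cutoff (3%) and with no
sustained suprathreshold pulse, hence *mild*. The CBF maps recover the
phantom's hypoperfused treated side (a 55% reduction at this noise level
and ROI size), the enhancing core reads 18.85% against a true 18.66%, and
six paired ROI means that all move the same way give the exact signed-rank
floor p = 2/2⁶ = 0.03125.

A configuration-driven study (groups, timepoints, per-subject scenarios)
runs through `run_pipeline(study_config(...))`, which writes `fixtures/`,
`doses/`, `maps/`, `histo/` and `report.json`. A thin CLI wrapper lives in
`inst/cli/sonoperm`.

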