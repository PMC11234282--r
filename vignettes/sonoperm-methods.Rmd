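---
title: "Models and methods behind sonoperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonoperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoperm)
```

`sonoperm` analyses microbubble-assisted focused-ultrasound (FUS)
blood–brain-barrier opening experiments: acoustic cavitation monitoring,
quantitative MRI, fluorescence histology and paired statistics. This
vignette explains the models, the constants that matter, what the bundled
simulators do and do not emulate, and the numerical conventions the
implementation commits to.

## Cavitation dose analysis

### Windowing

Ultrasound is delivered as 50 ms bursts at 1 Hz (duty cycle 5%, capped to
avoid heating) for 60 s, while a passive cavitation detector (PCD) records
acoustic emissions at 15.625 MHz. Each burst is analysed intrapulse: the
first 200 µs are discarded (non-linear switching transients of the
transducer), the signal is then split into contiguous 200 µs windows, and
the last 400 µs are discarded (end-of-burst distortions). With the default
layout this yields

```{r}
layout_dims(window_layout(), pulse_length = 0.050, sampling_rate = 15.625e6)
```

247 windows of 3125 samples — every analysed sample exactly once, head and
tail never analysed.

### Band powers and the dose matrices

Stable cavitation radiates at harmonics of the 1.5 MHz transmit frequency
f₀; the onset of inertial cavitation shows as ultra-harmonics, and violent
collapse as broadband noise. Per window the package computes a plain DFT
(no taper by default; a Hann taper with coherent-gain compensation is
available by flag) and integrates the one-sided power spectrum over
[fc − 25 kHz, fc + 25 kHz) around each band center — closed-open on the
discrete frequency grid, so a bin on the lower edge is included and one on
the upper edge is not. The normalisation is fixed and documented: a
unit-amplitude sinusoid at a band center contributes power 1/2 (A²/2 for
amplitude A). The intrapulse ultra-harmonic dose (IUD) sums the bands at
{1.5, 2.5, 3.5}·f₀, the harmonic dose (IHD) those at {2, 3, 4}·f₀. At the
standard settings the 200 µs window gives a 5 kHz bin width, so each 50 kHz
band integrates 10 bins.

### Noise reference, events, classification

The method needs no pre-injection baseline: the noise level is referenced
from the recording itself, by default the median of the lowest 25% of all
IUD values (robust to sparse bursts: with 5% of windows contaminated at
100× the floor, the estimate stays within 5% of the true floor). A window
is an *inertial event* when IUD/noise exceeds a threshold multiplier; runs
of at least `run_min` flagged windows within one pulse (runs never span
pulse boundaries) are *consecutive events*. Both are reported as
percentages of all analysed windows.

Three constants drive the verdict, all config-exposed and echoed in every
output because the underlying study communicates them only graphically:

| constant | default | rationale |
|---|---|---|
| `threshold_multiplier` | 6 | relative signal IUD/noise; consistent with a noise-band depiction roughly 6× below the inertial threshold |
| `run_min` | 2 | the weakest reading of "consecutive"; exposed in case ≥ 3 is wanted |
| soft cutoffs | 1.4% / 0.3% | the maxima observed in soft-classified animals (total and consecutive event fractions) |
| hard cutoff | 3% | midway between the soft maxima and the mild/hard extremes (≈ 6.3% / 6%) |

A sonication is **hard** when some pulse's *mean* relative signal stays
above the threshold (the sustained-suprathreshold signature of a
haemorrhagic case) or the consecutive fraction exceeds the hard cutoff;
otherwise **soft** when both fractions are within the soft cutoffs, else
**mild**. Because the operative soft rule could also be read strictly as
"no event at all", both are provided (`soft_mode = "maxima"` or
`"no_events"`). Verdicts are scale invariant — multiplying the whole
recording by a constant changes neither event fractions nor labels — and
monotone in burst amplitude and run length.

## Quantitative MRI

All quantifications assume co-registered magnitude images; registration,
distortion correction and atlas work are out of scope.

- **T1 (s)** from an 18-point inversion-recovery series (TIs 30 ms – 10 s,
  log-spaced): per-voxel fit of |M₀(1 − 2κ e^(−TI/T1))|. The magnitude
  data's polarity is restored around the signal minimum; for a fixed T1 the
  model is then linear in (M₀, M₀κ), so T1 is located on a 48-point
  logarithmic grid (0.05–10 s) solved vectorised across voxels, and refined
  per voxel by one-dimensional minimisation (tolerance 1e-8). Flat series
  and non-physical fits (M₀ ≤ 0) are flagged non-converged and masked.
- **CBF (mL/100g/min)**: ΔM = mean(control) − mean(label) over 30
  repetitions, then the single-compartment pCASL model
  CBF = 6000·λ·ΔM·e^(PLD/T1) / (2·α·T1·M₀·(1 − e^(−τ/T1))) with label
  duration τ = 3 s, post-labelling delay 0.3 s, partition coefficient
  λ = 0.9 mL/g, per-voxel measured T1 (not a fixed blood T1) and M₀ from
  the IR fit. The inversion efficiency α comes from a downstream vessel
  slice as mean |control − label| / (2|control|), clipped to (0, 1]; a
  scalar α is applied (a per-voxel α map would require interpolation to
  the ASL grid, which the package leaves to the caller).
- **BVf (%)**: R2\* by log-linear least squares over the 8 echoes
  (TE₁ = 3.5 ms, ΔTE = 5 ms) pre and post USPIO injection;
  BVf = 100·(3/4π)·ΔR2\*/(γ·Δχ·B₀) with γ = 2.675e8 rad/s/T and B₀ = 4.7 T.
  The susceptibility difference Δχ of the iron dose is not published for
  this agent; the default 1e-7 (SI) maps healthy-tissue BVf of 3–4% to
  ΔR2\* ≈ 16–21 s⁻¹, a typical steady-state USPIO value, and is a required,
  logged configuration constant.
- **ADC (mm²/s)**: tensor mode (default) fits ln(Sᵢ/S₀) = −b·gᵢᵀDgᵢ by
  linear least squares over 30 directions (b = 1000 s/mm²) and reports
  trace(D)/3; direction-average mode reports mean ln(S₀/Sᵢ)/b. The two
  agree exactly (to 1e-12) on isotropic noiseless voxels; tensor-trace is
  the default because vendor reconstructions compute ADC from tensor fits.
- **Gd enhancement (%)**: 100·(post − pre)/pre, with the opened region
  delineated automatically as 6-connected components of voxels whose
  difference exceeds k·SD (k = 3) of the difference in a contralateral
  reference region — a reproducible stand-in for manual outlining, and
  invariant to global intensity rescaling.
- Negative ΔM or ΔR2\* voxels are clipped to zero with a QC flag map
  rather than dropped, keeping maps defined everywhere for ROI statistics.
- **Exposure**: in-situ pressure = free-field × skull transmission ×
  exp(−α·f·depth) with brain attenuation α = 5 Np/m/MHz; mechanical index
  MI = PNP/√f (MPa, MHz).

## Histology

Marker quantification reduces to intensity thresholding (Otsu on the ROI
histogram by default, fixed level optionally) because the published
quantities — area fraction and mean intensity — are classifier-agnostic;
a trained pixel classifier would not be reproducible from text. Vessels
are skeletonised (Zhang–Suen thinning), split at junctions (pixels whose
8-neighbourhood crossing number is ≥ 3 — plain neighbour counts would
fragment smooth curves at staircase corners), and each segment's main
centerline is the weighted shortest path between its two most distant
skeleton pixels. Path length sums centerline steps (1 or √2 px), with the
junction pixel counted into every incident segment's length but never its
diameter; diameter is twice the half-pixel-corrected mean distance
transform along the centerline (resolution inherently ±1 px by parity of
the drawn width); tortuosity = path/chord ≥ 1. Segments under 3 centerline
pixels are discarded and counted. Red-blood-cell extravasation sites are
single-linkage clusters at a 50 µm radius (unstated in the source;
config-exposed) containing at least 5 cells.

## Statistics

The paired nonparametric comparison is the exact two-tailed Wilcoxon
signed-rank test — the "non-parametric two-tailed paired t-test" of the
study's methods section, named as Wilcoxon in its figure captions. Zero
differences are dropped (count reported), ties mid-ranked. For n ≤ 25 the
null distribution of the positive-rank sum is computed by convolution over
the doubled (hence integer) ranks, which is mathematically identical to
enumerating all 2ⁿ sign assignments; beyond that a normal approximation
with tie and continuity corrections is used. The two-tailed p is
min(1, 2·min(P(W′ ≤ W), P(W′ ≥ W))) — with six pairs all moving one way
this gives the floor 2/64 = 0.03125, with seven 2/128 = 0.015625.

Headline percent reductions are 100·(1 − ipsi/contra), rounded to the
nearest integer with ties away from zero. Reports carry the change under
both conventions — ratio of group means and mean of per-subject ratios —
because the two differ and a printed headline number is generally not
attributable to one of them: e.g. printed cortex-CBF group means of
42.24/93.57 give 54.9% by ratio of means, which rounds to 55, not the 54
a per-subject convention may have produced. No multiplicity correction is
applied, matching the source analyses.

## Synthetic data: what it does and does not emulate

The simulators are the package's test bed and define its study conditions.

- `simulate_pcd` renders each burst as a sum of sinusoids at the
  configured harmonic/ultra-harmonic frequencies, white Gaussian
  background, band-limited (0.3–6 MHz, covering all monitored bands below
  Nyquist) broadband segments confined to designated analysis windows, and
  an optional decaying chirp confined to the first 200 µs so the head cut
  is exercised. It does not model wave propagation, bubble dynamics
  (Rayleigh–Plesset), skull aberration, or absolute pressure calibration —
  amplitudes are arbitrary units, which suffices because every downstream
  decision is relative to the recording's own noise.
- `simulate_mri` generates acquisitions at signal-equation level (no
  k-space, no motion/EPI artefacts), as the exact forward models of the
  quantifications, with Rician noise (Gaussian on both quadrature
  channels before the magnitude; a Gaussian flag exists for debugging).
  Round-trip recovery at zero noise is therefore a correctness check of
  the fitting code, not evidence about in-vivo accuracy.
- `make_phantom` defaults to a 64×64×8 slab at 0.234×0.234×1.5 mm (the
  perfusion EPI grid) with mirrored contralateral/ipsilateral halves and
  an enhancing core occupying 5% of the treated ROI; tissue defaults are
  healthy rat cortex perfusion (93.57 mL/100g/min) against a hypoperfused
  treated side (42.24), BVf 3.9/3.4%, uniform ADC 1e-3 mm²/s, T1 1.7 s at
  4.7 T, and an 18.66% enhancing core.
- `simulate_fluorescence` renders parametric cells, tubes and point
  clusters with exact truth masks; it does not emulate optics (PSF,
  bleed-through, vignetting) or staining variability.

Consequently, passing tests demonstrate that the analysis chain inverts
its own forward models and honours its documented invariants — they do not
validate the biological models themselves against scanner or microscope
data.

## Problem sizes and determinism

Tests and the bundled study configurations run at desk scale by the
package's own choice: 5 ms bursts × 10 pulses for cavitation cohorts
(event fractions are scale-free percentages, and scenario templates place
bursts proportionally to the window count, so verdicts transfer to the
full 50 ms × 60 protocol, which the window-layout tests cover directly)
and 16×16×2 phantoms for Monte-Carlo MRI recovery (ROI-mean bias is the
tested quantity; 100 seeded phantoms at 0.5% noise of M₀ bound it below
2%). Every stochastic component takes an explicit integer seed and
identical configuration yields byte-identical fixtures and reports; the
pipeline embeds an FNV-1a hash of its configuration in every artifact.

## Known limitations

- No registration, masking, partial-volume or motion handling; volumes
  must arrive co-registered.
- The Δχ of the USPIO dose is a calibration constant, not a measured
  value; absolute BVf scales with it (doubling Δχ halves BVf exactly).
- Scalar inversion efficiency; no per-voxel α interpolation.
- Diameter estimates are limited to ±1 px by skeleton discretization.
- PCD amplitudes are uncalibrated (a.u.); only relative quantities are
  interpreted.
- The hard/mild boundary is a configurable convention: the single hard
  case in the motivating data was identified by sustained suprathreshold
  signal plus histology, not by a numeric cutoff.
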