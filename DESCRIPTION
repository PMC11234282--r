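Package: sonoperm
Title: Quantitative Analysis of Focused-Ultrasound Blood-Brain-Barrier Opening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for microbubble-assisted focused-ultrasound (FUS)
    blood-brain-barrier (BBB) opening experiments. Computes intrapulse
    ultra-harmonic and harmonic cavitation doses from passive cavitation
    detector recordings, detects inertial cavitation events against a
    noise-referenced threshold and classifies sonications as soft, mild or
    hard; quantifies parametric MRI maps (T1 by inversion recovery, cerebral
    blood flow by pseudo-continuous arterial spin labelling, blood volume
    fraction by steady-state delta-R2*, apparent diffusion coefficient,
    gadolinium enhancement with opened-volume delineation); quantifies
    fluorescence histology (marker area fraction and intensity, vessel
    morphometry, red-blood-cell extravasation sites); and assembles paired
    region-of-interest statistics with an exact Wilcoxon signed-rank test.
    Includes seeded simulators for acoustic recordings, MR acquisitions and
    fluorescence images with known ground truth, so the full pipeline is
    testable end-to-end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    withr,
    EBImage
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
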