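#' Digital phantom with known parametric ground truth
#'
#' A slab geometry mimicking a coronal rodent acquisition: the left half of
#' the brain slab is the contralateral ROI (label 1), the right half the
#' ipsilateral ROI (label 2), and a core region inside the ipsilateral ROI
#' (label 3) is the BBB-opened area carrying gadolinium enhancement.
#' Label 0 is background. Each voxel carries ground-truth CBF
#' (mL/100g/min), blood volume fraction (\%), ADC (mm^2/s), T1 (s) and
#' Gd enhancement (\%).
#'
#' Default tissue values reflect healthy rat cortex perfusion with a
#' hypoperfused treated side, a 3-4\% blood volume fraction with mild
#' vasoconstriction, uniform diffusion (no cytotoxic oedema), and an 18.66\%
#' enhancing core occupying 5\% of the ipsilateral ROI.
#'
#' @param dim Integer triplet, voxel grid (default 64 x 64 x 8).
#' @param voxel_size mm triplet (default 0.234 x 0.234 x 1.5, the perfusion
#'   EPI grid).
#' @param values List of per-region truth values; each of `cbf`, `bvf`,
#'   `adc`, `t1`, `enhancement` is a named vector with entries `contra`,
#'   `ipsi` and (for enhancement) `core`.
#' @param core_fraction Fraction of the ipsilateral ROI converted to the
#'   enhancing core (default 0.05).
#' @param seed Integer seed (reserved for randomised geometries; the default
#'   geometry is deterministic).
#' @return A `phantom`: list of `label_map` and truth arrays plus geometry.
#' @export
make_phantom <- function(dim = c(64L, 64L, 8L),
                         voxel_size = c(0.234, 0.234, 1.5),
                         values = list(
                           cbf = c(contra = 93.57, ipsi = 42.24),
                           bvf = c(contra = 3.9, ipsi = 3.4),
                           adc = c(contra = 1.0e-3, ipsi = 1.0e-3),
                           t1 = c(contra = 1.7, ipsi = 1.7),
                           enhancement = c(contra = 0, ipsi = 0, core = 18.66)),
                         core_fraction = 0.05,
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= c(4, 4, 1)), length(voxel_size) == 3)
  dim <- as.integer(dim)
  lab <- array(0L, dim)
  # brain slab with a 1-voxel background rim in-plane
  xr <- 2:(dim[1] - 1); yr <- 2:(dim[2] - 1)
  lab[xr, yr, ] <- 1L
  mid <- dim[1] %/% 2
  lab[(mid + 1):(dim[1] - 1), yr, ] <- 2L
  # enhancing core: contiguous block inside the ipsilateral ROI
  n_ipsi <- sum(lab == 2L)
  n_core <- max(1L, round(core_fraction * n_ipsi))
  ipsi_idx <- which(lab == 2L)
  lab[ipsi_idx[seq_len(n_core)]] <- 3L

  fill <- function(vals, core = vals[["ipsi"]]) {
    a <- array(0, dim)
    a[lab == 1L] <- vals[["contra"]]
    a[lab == 2L] <- vals[["ipsi"]]
    a[lab == 3L] <- core
    a
  }
  enh <- array(0, dim)
  enh[lab == 1L] <- values$enhancement[["contra"]]
  enh[lab == 2L] <- values$enhancement[["ipsi"]]
  enh[lab == 3L] <- values$enhancement[["core"]]

  structure(list(label_map = lab,
                 truth_cbf = fill(values$cbf),
                 truth_bvf = fill(values$bvf),
                 truth_adc = fill(values$adc),
                 truth_t1 = fill(values$t1),
                 truth_enhancement = enh,
                 voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "phantom")
}

#' Region masks of a phantom
#'
#' @param phantom A `phantom`.
#' @return List of logical arrays: `brain`, `contra`, `ipsi` (includes the
#'   core), `core`.
#' @export
phantom_masks <- function(phantom) {
  lab <- phantom$label_map
  list(brain = lab > 0L,
       contra = lab == 1L,
       ipsi = lab == 2L | lab == 3L,
       core = lab == 3L)
}
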