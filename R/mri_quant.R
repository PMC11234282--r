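#' Parametric map container
#'
#' @param values 3-D numeric array in the map's physical unit.
#' @param voxel_size mm triplet.
#' @param mask Logical array of valid voxels; non-finite values are confined
#'   outside the mask.
#' @param unit Character unit label.
#' @param provenance Named list snapshot of the constants used.
#' @return A `quant_map`.
#' @export
quant_map <- function(values, voxel_size, mask = NULL, unit = "",
                      provenance = list()) {
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, voxel_size = voxel_size, mask = mask,
                 unit = unit, provenance = provenance),
            class = "quant_map")
}

# Solve the per-voxel linear subproblem of the magnitude-IR model for a
# fixed T1: signed signal ~ c1 + c2 * exp(-TI/T1). S is nTI x V (already
# sign-restored). Returns list(coef = 2 x V, rss = V).
.ir_linfit <- function(S, tis, t1) {
  x <- exp(-tis / t1)
  n <- length(tis)
  sx <- sum(x); sxx <- sum(x * x)
  det <- n * sxx - sx * sx
  sy <- colSums(S); sxy <- as.vector(crossprod(x, S))
  c1 <- (sxx * sy - sx * sxy) / det
  c2 <- (n * sxy - sx * sy) / det
  fit <- outer(rep(1, n), c1) + outer(x, c2)
  rss <- colSums((S - fit)^2)
  list(c1 = c1, c2 = c2, rss = rss)
}

#' Fit T1 from a magnitude inversion-recovery series
#'
#' Per-voxel three-parameter fit of |M0 (1 - 2 kappa exp(-TI/T1))|.
#' Polarity of the magnitude data is restored around the signal minimum
#' (the nulled samples), after which the model is linear in (M0, M0 kappa)
#' for fixed T1; T1 is found on a coarse logarithmic grid and refined by
#' one-dimensional minimisation. Voxels with a flat series or a
#' non-physical fit are flagged non-converged and masked out.
#'
#' @param ir_series 4-D array (x, y, z, TI) of magnitude signals, or output
#'   list of `simulate_mri(kind = "ir_t1")`.
#' @param tis Inversion times in seconds (defaults to the series' own).
#' @param voxel_size mm triplet for the returned maps.
#' @param mask Optional logical array restricting the fit.
#' @param t1_grid Candidate T1 grid in seconds.
#' @return List of `quant_map`s: `t1` (s), `m0` (a.u.), `kappa`
#'   (inversion factor), plus logical `converged`.
#' @export
fit_t1 <- function(ir_series, tis = NULL, voxel_size = c(1, 1, 1),
                   mask = NULL,
                   t1_grid = exp(seq(log(0.05), log(10), length.out = 48))) {
  if (is.list(ir_series) && !is.null(ir_series$series)) {
    if (is.null(tis)) tis <- ir_series$tis
    ir_series <- ir_series$series
  }
  stopifnot(length(dim(ir_series)) == 4, length(tis) == dim(ir_series)[4])
  if (length(tis) < 3) stop("need at least 3 inversion times")
  dm <- dim(ir_series)[1:3]
  nti <- length(tis)
  S_all <- t(matrix(ir_series, prod(dm), nti))   # nTI x V
  if (is.null(mask)) mask <- array(TRUE, dm)
  use <- as.vector(mask) & colSums(abs(S_all)) > 0 &
    (apply(S_all, 2, max) - apply(S_all, 2, min)) > 1e-9 * apply(S_all, 2, max)
  V <- sum(use)
  t1v <- rep(NA_real_, prod(dm)); m0v <- rep(NA_real_, prod(dm))
  kv <- rep(NA_real_, prod(dm)); conv <- rep(FALSE, prod(dm))
  if (V > 0) {
    S <- S_all[, use, drop = FALSE]
    kmin <- apply(S, 2, which.min)
    row_i <- matrix(seq_len(nti), nti, V)
    best_rss <- rep(Inf, V); best_t1 <- rep(NA_real_, V)
    best_d <- rep(0L, V); best_c1 <- rep(NA_real_, V); best_c2 <- rep(NA_real_, V)
    for (d in c(-1L, 0L, 1L)) {
      j <- pmin(pmax(kmin + d, 0L), nti)
      sgn <- ifelse(row_i <= matrix(j, nti, V, byrow = TRUE), -1, 1)
      Ssig <- S * sgn
      for (t1 in t1_grid) {
        f <- .ir_linfit(Ssig, tis, t1)
        upd <- f$rss < best_rss
        best_rss[upd] <- f$rss[upd]; best_t1[upd] <- t1
        best_d[upd] <- d; best_c1[upd] <- f$c1[upd]; best_c2[upd] <- f$c2[upd]
      }
    }
    # per-voxel refinement around the grid optimum
    for (v in seq_len(V)) {
      j <- min(max(kmin[v] + best_d[v], 0L), nti)
      s <- S[, v] * ifelse(seq_len(nti) <= j, -1, 1)
      gi <- which.min(abs(t1_grid - best_t1[v]))
      lo <- t1_grid[max(1L, gi - 1L)]; hi <- t1_grid[min(length(t1_grid), gi + 1L)]
      obj <- function(t1) .ir_linfit(matrix(s, ncol = 1), tis, t1)$rss
      op <- stats::optimize(obj, c(lo, hi), tol = 1e-8)
      f <- .ir_linfit(matrix(s, ncol = 1), tis, op$minimum)
      best_t1[v] <- op$minimum; best_c1[v] <- f$c1; best_c2[v] <- f$c2
      best_rss[v] <- f$rss
    }
    ok <- best_c1 > 0 & best_c2 < 0 & is.finite(best_t1)
    idx <- which(use)
    t1v[idx[ok]] <- best_t1[ok]
    m0v[idx[ok]] <- best_c1[ok]
    kv[idx[ok]] <- -best_c2[ok] / (2 * best_c1[ok])
    conv[idx[ok]] <- TRUE
  }
  cmask <- array(conv, dm)
  list(t1 = quant_map(array(t1v, dm), voxel_size, cmask, "s"),
       m0 = quant_map(array(m0v, dm), voxel_size, cmask, "a.u."),
       kappa = quant_map(array(kv, dm), voxel_size, cmask, ""),
       converged = cmask)
}

#' Labelling inversion efficiency from a downstream vessel slice
#'
#' alpha = mean over the vessel mask of |control - label| / (2 |control|),
#' clipped to (0, 1]. Zero inversion (label equal to control) is an error.
#'
#' @param control,label Numeric arrays (a.u.).
#' @param vessel_mask Logical array selecting vessel voxels.
#' @return Scalar alpha in (0, 1].
#' @export
inversion_efficiency <- function(control, label, vessel_mask) {
  stopifnot(any(vessel_mask))
  c_v <- control[vessel_mask]; l_v <- label[vessel_mask]
  if (any(c_v == 0)) stop("zero control signal inside the vessel mask")
  alpha <- mean(abs(c_v - l_v) / (2 * abs(c_v)))
  if (alpha == 0) stop("no inversion: label equals control in the vessel mask")
  min(alpha, 1)
}

#' Quantify cerebral blood flow from a pCASL series
#'
#' Single-compartment pCASL model with per-voxel measured T1:
#' CBF = 6000 lambda dM exp(PLD/T1) / (2 alpha T1 M0 (1 - exp(-tau/T1)))
#' in mL/100g/min, where dM is the mean control minus mean label signal.
#' Negative dM voxels are clipped to zero and flagged.
#'
#' @param asl pCASL acquisition: list with `control` and `label` 4-D arrays
#'   (x, y, z, repetition), e.g. from `simulate_mri(kind = "pcasl")`.
#' @param t1_map 3-D array of T1 (s) on the ASL grid.
#' @param m0_map 3-D array of equilibrium magnetisation (a.u.).
#' @param alpha Inversion efficiency scalar in (0, 1].
#' @param lambda Blood-brain partition coefficient, mL/g.
#' @param label_duration,post_label_delay Seconds.
#' @param voxel_size mm triplet.
#' @param mask Optional logical array.
#' @return A `quant_map` (mL/100g/min) with a `clipped` flag array attached
#'   to the provenance.
#' @export
quantify_cbf <- function(asl, t1_map, m0_map, alpha = 0.85, lambda = 0.9,
                         label_duration = 3.0, post_label_delay = 0.3,
                         voxel_size = c(1, 1, 1), mask = NULL) {
  stopifnot(alpha > 0, alpha <= 1, label_duration > 0, post_label_delay > 0)
  stopifnot(identical(dim(asl$control), dim(asl$label)))
  dM <- apply(asl$control, 1:3, mean) - apply(asl$label, 1:3, mean)
  dm <- dim(dM)
  if (is.null(mask)) mask <- t1_map > 0 & m0_map > 0
  if (any(mask & (t1_map <= 0 | m0_map <= 0)))
    stop("nonpositive T1 or M0 inside the mask")
  clipped <- mask & dM < 0
  dM[clipped] <- 0
  cbf <- array(NA_real_, dm)
  cbf[mask] <- 6000 * lambda * dM[mask] * exp(post_label_delay / t1_map[mask]) /
    (2 * alpha * t1_map[mask] * m0_map[mask] *
       (1 - exp(-label_duration / t1_map[mask])))
  quant_map(cbf, voxel_size, mask, "mL/100g/min",
            provenance = list(alpha = alpha, lambda = lambda,
                              label_duration = label_duration,
                              post_label_delay = post_label_delay,
                              clipped = clipped))
}

# Vectorized log-linear R2* fit: series is 4-D (x, y, z, echo).
.fit_r2s <- function(series, tes, mask) {
  dm <- dim(series)[1:3]
  ne <- length(tes)
  S <- t(matrix(series, prod(dm), ne))          # echoes x V
  use <- as.vector(mask) & apply(S > 0, 2, all)
  y <- log(S[, use, drop = FALSE])
  tbar <- mean(tes); den <- sum((tes - tbar)^2)
  # per-voxel OLS slope of log-signal vs TE; -slope is R2*
  slope <- as.vector(crossprod(tes - tbar, y)) / den
  r2s <- rep(NA_real_, prod(dm))
  r2s[use] <- -slope
  array(r2s, dm)
}

#' Quantify blood volume fraction from pre/post-USPIO multi-echo series
#'
#' Per-voxel R2* from a log-linear least-squares fit of signal versus echo
#' time, before and after the intravascular iron-oxide injection;
#' BVf[\%] = 100 (3 / 4 pi) dR2* / (gamma delta_chi B0). Negative dR2*
#' voxels are clipped to zero and flagged.
#'
#' @param mge Acquisition list with `pre`, `post` (4-D arrays x, y, z, echo)
#'   and `tes` (s), e.g. from `simulate_mri(kind = "mge_pre_post")`.
#' @param constants [susceptibility_constants()].
#' @param voxel_size mm triplet.
#' @param mask Optional logical array.
#' @return A `quant_map` (\%) with `clipped` flag array and the dR2* map in
#'   the provenance.
#' @export
quantify_bvf <- function(mge, constants = susceptibility_constants(),
                         voxel_size = c(1, 1, 1), mask = NULL) {
  tes <- mge$tes
  if (length(tes) < 3) stop("need at least 3 echoes")
  if (any(diff(tes) <= 0)) stop("echo times must be strictly increasing")
  stopifnot(identical(dim(mge$pre), dim(mge$post)))
  dm <- dim(mge$pre)[1:3]
  if (is.null(mask)) mask <- apply(mge$pre > 0, 1:3, all)
  r2s_pre <- .fit_r2s(mge$pre, tes, mask)
  r2s_post <- .fit_r2s(mge$post, tes, mask)
  dr2s <- r2s_post - r2s_pre
  clipped <- !is.na(dr2s) & dr2s < 0
  dr2s[clipped] <- 0
  bvf <- 100 * (3 / (4 * pi)) * dr2s /
    (constants$gamma * constants$delta_chi * constants$b0)
  quant_map(bvf, voxel_size, mask & is.finite(bvf), "%",
            provenance = c(constants, list(clipped = clipped, dr2s = dr2s)))
}

#' Quantify the apparent diffusion coefficient
#'
#' Tensor mode (default) fits the diffusion tensor by linear least squares
#' of ln(S_i/S_0) = -b g_i' D g_i over the encoding directions and reports
#' ADC = trace(D)/3; direction-average mode reports the mean of
#' ln(S_0/S_i)/b. The two agree exactly for isotropic voxels.
#'
#' @param dwi Acquisition list with `b0` (3-D), `dwi` (4-D x, y, z,
#'   direction), `bval` (s/mm^2) and `directions` (n x 3 unit vectors).
#' @param mode `"tensor"` or `"mean"`.
#' @param voxel_size mm triplet.
#' @param mask Optional logical array.
#' @return A `quant_map` (mm^2/s).
#' @export
quantify_adc <- function(dwi, mode = c("tensor", "mean"),
                         voxel_size = c(1, 1, 1), mask = NULL) {
  mode <- match.arg(mode)
  g <- dwi$directions
  nd <- nrow(g)
  dm <- dim(dwi$b0)
  if (is.null(mask)) mask <- dwi$b0 > 0
  S <- t(matrix(dwi$dwi, prod(dm), nd))         # directions x V
  use <- as.vector(mask) & as.vector(dwi$b0 > 0) & apply(S > 0, 2, all)
  Y <- log(sweep(1 / S[, use, drop = FALSE], 2, as.vector(dwi$b0)[use], "*"))
  adc <- rep(NA_real_, prod(dm))
  if (mode == "mean") {
    adc[use] <- colMeans(Y) / dwi$bval
  } else {
    if (nd < 6) stop("tensor mode needs at least 6 non-collinear directions")
    G <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
               2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
    coefs <- solve(crossprod(G), crossprod(G, Y / dwi$bval))   # 6 x V
    adc[use] <- colSums(coefs[1:3, , drop = FALSE]) / 3
  }
  quant_map(array(adc, dm), voxel_size, array(use, dm), "mm^2/s",
            provenance = list(mode = mode, bval = dwi$bval))
}

# 6-connected 3-D component labelling (small volumes; BFS flood fill).
label_components_3d <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]; queue <- queue[-length(queue)]
      ai <- arrayInd(i, dm)
      for (k in seq_len(6)) {
        p <- ai + nb[k, ]
        if (any(p < 1) || any(p > dm)) next
        j <- p[1] + (p[2] - 1L) * dm[1] + (p[3] - 1L) * dm[1] * dm[2]
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Gadolinium enhancement and opened-volume delineation
#'
#' Voxelwise enhancement 100 (post - pre) / pre, and an automated stand-in
#' for manual outlining of the opened region: voxels whose pre/post
#' difference exceeds `k` standard deviations of the difference in a
#' contralateral reference region, grouped into 6-connected components.
#' The delineation is invariant to a global intensity rescaling of both
#' images.
#'
#' @param t1w_pre,t1w_post Co-registered 3-D arrays (a.u.).
#' @param roi Logical array: region over which the mean enhancement is
#'   reported (e.g. the targeted cortex or striatum).
#' @param ref_mask Logical array: contralateral reference region for the
#'   noise SD of the difference image.
#' @param k Threshold multiplier (default 3).
#' @param voxel_size mm triplet.
#' @param min_component Minimum component size in voxels kept (default 1).
#' @return List: `enhancement` (`quant_map`, \%), `opened_mask`,
#'   `opened_volume_mm3`, `mean_enhancement` (\% over roi-and-opened voxels,
#'   `NA` if none).
#' @export
gd_enhancement <- function(t1w_pre, t1w_post, roi, ref_mask, k = 3,
                           voxel_size = c(1, 1, 1), min_component = 1L) {
  stopifnot(identical(dim(t1w_pre), dim(t1w_post)))
  if (any(roi & t1w_pre <= 0)) stop("zero pre-contrast signal inside the ROI")
  diffim <- t1w_post - t1w_pre
  valid <- t1w_pre > 0
  enh <- array(NA_real_, dim(t1w_pre))
  enh[valid] <- 100 * diffim[valid] / t1w_pre[valid]
  sd_ref <- stats::sd(diffim[ref_mask])
  if (!is.finite(sd_ref)) sd_ref <- 0
  cand <- valid & diffim > k * sd_ref
  lab <- label_components_3d(cand)
  if (min_component > 1L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    cand <- cand & array(sizes[pmax(lab, 1L)] >= min_component, dim(lab)) & lab > 0L
  }
  opened <- cand
  sel <- opened & roi
  list(enhancement = quant_map(enh, voxel_size, valid, "%",
                               provenance = list(k = k, sd_ref = sd_ref)),
       opened_mask = opened,
       opened_volume_mm3 = sum(opened) * prod(voxel_size),
       mean_enhancement = if (any(sel)) mean(enh[sel]) else NA_real_)
}

#' Derate free-field pressure to in-situ pressure
#'
#' in-situ PNP = free-field PNP x skull transmission x
#' exp(-alpha_brain f depth), with the brain attenuation alpha in
#' Np/m/MHz and f in MHz.
#'
#' @param free_field_pnp MPa.
#' @param f MHz.
#' @param brain_depth m.
#' @param alpha_brain Np/m/MHz (default 5).
#' @param skull_transmission Amplitude transmission factor in (0, 1].
#' @return In-situ PNP, MPa.
#' @export
derate_pressure <- function(free_field_pnp, f, brain_depth,
                            alpha_brain = 5, skull_transmission = 1) {
  stopifnot(free_field_pnp > 0, f > 0, alpha_brain >= 0,
            skull_transmission > 0, skull_transmission <= 1)
  if (brain_depth < 0) stop("brain depth must be >= 0")
  free_field_pnp * skull_transmission * exp(-alpha_brain * f * brain_depth)
}

#' Mechanical index
#'
#' MI = PNP / sqrt(f), PNP in MPa and f in MHz.
#'
#' @param pnp Peak negative pressure, MPa.
#' @param f Frequency, MHz.
#' @return Dimensionless MI.
#' @export
mechanical_index <- function(pnp, f) {
  stopifnot(pnp > 0, f > 0)
  pnp / sqrt(f)
}
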