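#' Emission scenario templates for the three exposure regimes
#'
#' Builds an [emission_scenario()] realising a soft (stable cavitation
#' only: harmonics over background noise), mild (isolated inertial events:
#' a few scattered broadband windows plus short runs) or hard (sustained
#' inertial cavitation: entire pulses above threshold) sonication under a
#' given protocol. Burst placement is seeded and scales with the number of
#' analysis windows, so the same regime classifies identically at any
#' desk-scale protocol.
#'
#' @param kind `"soft"`, `"mild"` or `"hard"`.
#' @param protocol A [fus_protocol()].
#' @param layout A [window_layout()].
#' @param seed Integer seed.
#' @param burst_sd Broadband spectral amplitude (a.u.); the default sits
#'   roughly 30x above the noise reference: unambiguous events that do not
#'   dominate a pulse mean at desk scale.
#' @param noise_sd Background white-noise SD (a.u.).
#' @return An [emission_scenario()].
#' @export
make_scenario <- function(kind = c("soft", "mild", "hard"), protocol,
                          layout = window_layout(), seed = 1L,
                          burst_sd = 0.05, noise_sd = 0.01) {
  kind <- match.arg(kind)
  dims <- layout_dims(layout, protocol$pulse_length, protocol$sampling_rate)
  nw <- dims$n_windows; np <- protocol$n_pulses
  total <- nw * np
  bursts <- withr::with_seed(seed + 7919L, switch(kind,
    soft = list(),
    mild = {
      # ~1.5% of windows in runs of 2 plus ~1.5% singletons: above the soft
      # maxima (1.4% / 0.3%) but below the hard consecutive cutoff (3%)
      n_runs <- max(1L, floor(0.0075 * total))
      n_single <- max(1L, floor(0.015 * total))
      b <- list()
      for (i in seq_len(n_runs)) {
        p <- sample.int(np, 1); w0 <- sample.int(max(1L, nw - 1L), 1)
        b[[length(b) + 1L]] <- list(pulse = p, windows = c(w0, min(w0 + 1L, nw)),
                                    sd = burst_sd)
      }
      for (i in seq_len(n_single)) {
        b[[length(b) + 1L]] <- list(pulse = sample.int(np, 1),
                                    windows = sample.int(nw, 1), sd = burst_sd)
      }
      b
    },
    hard = {
      # sustained suprathreshold signal: several whole pulses flagged
      ps <- sample.int(np, max(2L, ceiling(0.1 * np)))
      lapply(ps, function(p) list(pulse = p, windows = seq_len(nw),
                                  sd = burst_sd))
    }))
  emission_scenario(harmonic_amps = c(0.05, 0.03, 0.02),
                    ultraharmonic_amps = c(0, 0, 0),
                    broadband_bursts = bursts,
                    background_noise_sd = noise_sd,
                    seed = seed)
}

#' Study configuration
#'
#' Builds (or loads from YAML) the configuration driving [run_pipeline()]:
#' group structure, exposure protocol, phantom geometry and truth values,
#' quantification constants and classification cutoffs, with one master
#' seed. The default is a desk-scale toy study; the in-vivo design
#' (three groups of 14, 14 and 9 animals over the 30min-7d timepoints) is
#' expressed by enlarging `groups`.
#'
#' @param path Optional YAML file; fields merge over the defaults.
#' @param ... Named fields merged over the defaults (after YAML).
#' @return A `study_config` list.
#' @export
study_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    groups = list(
      list(name = "g1", n = 2L, target = "cortex",
           timepoints = "30min", gd = TRUE,
           scenarios = c("soft", "mild")),
      list(name = "g2", n = 1L, target = "striatum",
           timepoints = "30min", gd = FALSE,
           scenarios = "soft")),
    protocol = list(pulse_length = 0.005, n_pulses = 10L),
    layout = list(head_cut = 200e-6, window_length = 200e-6,
                  tail_cut = 400e-6),
    phantom = list(dim = c(16L, 16L, 2L), voxel_size = c(0.234, 0.234, 1.5)),
    mri = list(noise_sd = 0.5, skip = character()),
    cavitation = list(threshold = 6, run_min = 2L,
                      cutoffs = list(soft_inertial = 1.4,
                                     soft_consecutive = 0.3, hard = 3)),
    histo = list(shape = c(64L, 64L), background_sd = 0.02),
    gd = list(k = 3)
  )
  merge_cfg <- function(base, over) {
    # groups is an unnamed list: replace wholesale (modifyList would skip it)
    grp <- over$groups
    over$groups <- NULL
    out <- utils::modifyList(base, over)
    if (!is.null(grp)) out$groups <- grp
    out
  }
  if (!is.null(path)) cfg <- merge_cfg(cfg, yaml::read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- merge_cfg(cfg, dots)
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

valid_timepoints <- c("30min", "60min", "90min", "24h", "d1", "d2", "d3", "d7")

validate_study_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$groups) >= 1)
  for (g in cfg$groups) {
    if (is.null(g$name) || is.null(g$n) || is.null(g$target))
      stop("each group needs name, n and target")
    if (!g$target %in% c("cortex", "striatum"))
      stop("group target must be 'cortex' or 'striatum'")
    if (!all(g$timepoints %in% valid_timepoints))
      stop("unknown timepoint in group ", g$name)
    if (!is.null(g$scenarios) && !all(g$scenarios %in% c("soft", "mild", "hard")))
      stop("group scenarios must be soft/mild/hard")
  }
  invisible(cfg)
}

# stable per-subject seed, kept well below 2^31
subject_seed <- function(master, group_i, subject_i, stage_i = 0L) {
  (as.integer(master) %% 10000L) * 100000L + group_i * 10000L +
    subject_i * 100L + stage_i
}

#' Run the analysis pipeline on a synthetic study
#'
#' Executes the requested stages over every subject of every group in the
#' configuration: `simulate` writes PCD and fixture data, `cavitation`
#' computes dose matrices and verdicts, `mri` forward-simulates the
#' acquisitions from each subject's phantom and quantifies all parametric
#' maps, `histo` renders and quantifies fluorescence fixtures, and
#' `report` assembles `report.json`. The output layout is deterministic
#' (`fixtures/`, `doses/`, `maps/`, `histo/`, `report.json`) and every
#' product embeds the configuration hash; re-running with the same
#' configuration is idempotent.
#'
#' @param config A [study_config()].
#' @param stages Subset of `c("simulate", "cavitation", "mri", "histo",
#'   "report")`.
#' @param out_dir Artifact directory (created).
#' @return Invisibly, the path of `out_dir`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "cavitation", "mri",
                                    "histo", "report"),
                         out_dir = tempfile("sonoperm_run_")) {
  stopifnot(inherits(config, "study_config"))
  stages <- match.arg(stages, c("simulate", "cavitation", "mri", "histo",
                                "report"), several.ok = TRUE)
  cfg_hash <- fnv1a_hash(yaml::as.yaml(unclass(config)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  protocol <- do.call(fus_protocol, config$protocol)
  layout <- do.call(window_layout, config$layout)
  cutoffs <- config$cavitation$cutoffs

  verdict_rows <- NULL; roi_rows <- NULL; histo_rows <- NULL
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    scen_kinds <- if (is.null(g$scenarios)) rep("soft", g$n) else
      rep(g$scenarios, length.out = g$n)
    for (si in seq_len(g$n)) {
      sid <- paste0(g$name, "_s", si)
      if ("simulate" %in% stages) {
        dir.create(file.path(out_dir, "fixtures"), showWarnings = FALSE)
        scen <- make_scenario(scen_kinds[si], protocol, layout,
                              seed = subject_seed(config$seed, gi, si, 1L))
        rec <- simulate_pcd(protocol, scen, layout)
        write_pcd(rec, file.path(out_dir, "fixtures", paste0(sid, "_pcd.bin")))
      }
      if ("cavitation" %in% stages) {
        binpath <- file.path(out_dir, "fixtures", paste0(sid, "_pcd.bin"))
        if (!file.exists(binpath))
          stop("missing upstream PCD fixture for ", sid,
               "; run the simulate stage first")
        rec <- read_pcd(binpath)
        res <- analyse_cavitation(rec, layout,
                                  threshold_multiplier = config$cavitation$threshold,
                                  run_min = config$cavitation$run_min,
                                  cutoffs = cutoffs)
        dir.create(file.path(out_dir, "doses"), showWarnings = FALSE)
        dd <- res$doses
        flat <- data.frame(pulse = as.vector(row(dd$iud)),
                           window = as.vector(col(dd$iud)),
                           iud = as.vector(dd$iud), ihd = as.vector(dd$ihd),
                           flag = as.vector(dd$event_flags))
        utils::write.csv(flat, file.path(out_dir, "doses",
                                         paste0(sid, "_doses.csv")),
                         row.names = FALSE)
        v <- res$verdict
        jsonlite::write_json(
          list(subject = sid, label = v$label,
               pct_inertial = v$pct_inertial,
               pct_consecutive = v$pct_consecutive,
               any_pulse_mean_above = v$any_pulse_mean_above,
               threshold = v$threshold_multiplier, cutoffs = v$cutoffs,
               config_hash = cfg_hash),
          file.path(out_dir, "doses", paste0(sid, "_verdict.json")),
          auto_unbox = TRUE, digits = NA)
        verdict_rows <- rbind(verdict_rows,
                              data.frame(subject = sid, group = g$name,
                                         label = v$label,
                                         pct_inertial = v$pct_inertial,
                                         pct_consecutive = v$pct_consecutive))
      }
      if ("mri" %in% stages) {
        dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
        ph <- make_phantom(dim = config$phantom$dim,
                           voxel_size = config$phantom$voxel_size)
        masks <- phantom_masks(ph)
        sseed <- subject_seed(config$seed, gi, si, 2L)
        noise <- config$mri$noise_sd
        maps <- quantify_phantom_session(ph, noise_sd = noise, seed = sseed,
                                         gd = isTRUE(g$gd), k = config$gd$k)
        for (nm in names(maps$maps))
          write_quant_map(maps$maps[[nm]],
                          file.path(out_dir, "maps",
                                    paste0(sid, "_", nm, ".nii.gz")))
        for (metric in names(maps$maps)) {
          m <- maps$maps[[metric]]
          roi_rows <- rbind(roi_rows, data.frame(
            group = g$name, timepoint = g$timepoints[1], metric = metric,
            subject = sid,
            ipsi = extract_roi(m, masks$ipsi)$mean,
            contra = extract_roi(m, masks$contra)$mean))
        }
      }
      if ("histo" %in% stages) {
        dir.create(file.path(out_dir, "histo"), showWarnings = FALSE)
        hseed <- subject_seed(config$seed, gi, si, 3L)
        shp <- config$histo$shape
        fx <- simulate_fluorescence(
          shp,
          objects = list(
            list(kind = "cell", center = round(shp / 3), radius = 4,
                 n_arms = 5, intensity = 1),
            list(kind = "vessel",
                 path = rbind(c(round(shp[1] * 0.7), 4),
                              c(round(shp[1] * 0.7), shp[2] - 4)),
                 radius = 2, intensity = 1)),
          background_sd = config$histo$background_sd, seed = hseed)
        roi <- matrix(TRUE, shp[1], shp[2])
        seg <- segment_marker(fx$image, roi, method = "otsu")
        hq <- quantify_roi(fx$image, seg, roi, roi_id = "ipsilateral",
                           marker = "GFAP")
        hq$subject <- sid; hq$group <- g$name
        histo_rows <- rbind(histo_rows, hq)
      }
    }
  }
  if ("report" %in% stages) {
    report <- assemble_report(roi_stats = roi_rows, verdicts = verdict_rows,
                              histology = histo_rows,
                              config = c(unclass(config),
                                         list(config_hash = cfg_hash)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Simulate and quantify one full MR session from a phantom
#'
#' Forward-simulates the inversion-recovery, pCASL, multi-gradient-echo,
#' DWI and (optionally) pre/post-gadolinium T1-weighted acquisitions from a
#' phantom and runs every quantification, returning the parametric maps.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param noise_sd Acquisition noise SD (a.u. per channel; the equilibrium
#'   signal is 100 a.u., so 0.5 is 0.5\% of M0).
#' @param seed Integer seed.
#' @param gd Simulate and quantify the gadolinium stage?
#' @param k Delineation threshold multiplier for [gd_enhancement()].
#' @return List: `maps` (named `quant_map`s: `t1`, `cbf`, `bvf`, `adc` and
#'   optionally `enhancement`), `gd` (full [gd_enhancement()] output or
#'   `NULL`).
#' @export
quantify_phantom_session <- function(phantom, noise_sd = 0, seed = 1L,
                                     gd = TRUE, k = 3) {
  masks <- phantom_masks(phantom)
  vs <- phantom$voxel_size
  ir <- simulate_mri(phantom, "ir_t1", noise_sd = noise_sd, seed = seed)
  t1fit <- fit_t1(ir, voxel_size = vs, mask = masks$brain)
  asl <- simulate_mri(phantom, "pcasl", noise_sd = noise_sd, seed = seed + 1L)
  cbf <- quantify_cbf(asl, t1_map = t1fit$t1$values, m0_map = t1fit$m0$values,
                      alpha = asl$params$alpha, lambda = asl$params$lambda,
                      label_duration = asl$params$label_duration,
                      post_label_delay = asl$params$post_label_delay,
                      voxel_size = vs,
                      mask = masks$brain & t1fit$converged)
  mge <- simulate_mri(phantom, "mge_pre_post", noise_sd = noise_sd,
                      seed = seed + 2L)
  bvf <- quantify_bvf(mge, constants = mge$params$constants, voxel_size = vs,
                      mask = masks$brain)
  dwi <- simulate_mri(phantom, "dwi", noise_sd = noise_sd, seed = seed + 3L)
  adc <- quantify_adc(dwi, voxel_size = vs, mask = masks$brain)
  maps <- list(t1 = t1fit$t1, cbf = cbf, bvf = bvf, adc = adc)
  gd_out <- NULL
  if (gd) {
    t1w <- simulate_mri(phantom, "t1w_pre_post_gd", noise_sd = noise_sd,
                        seed = seed + 4L)
    gd_out <- gd_enhancement(t1w$pre, t1w$post, roi = masks$ipsi,
                             ref_mask = masks$contra, k = k, voxel_size = vs)
    maps$enhancement <- gd_out$enhancement
  }
  list(maps = maps, gd = gd_out)
}
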