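test_that("magnitude inversion-recovery fit recovers T1, M0 and kappa", {
  t1_true <- c(0.5, 1.2, 2.1, 3.0)
  ph <- make_phantom(dim = c(4, 4, 1),
                     values = list(cbf = c(contra = 50, ipsi = 50),
                                   bvf = c(contra = 3, ipsi = 3),
                                   adc = c(contra = 1e-3, ipsi = 1e-3),
                                   t1 = c(contra = 1, ipsi = 1),
                                   enhancement = c(contra = 0, ipsi = 0,
                                                   core = 0)))
  # overwrite with a spread of T1 values inside the brain
  brain <- ph$label_map > 0
  ph$truth_t1[brain] <- rep(t1_true, length.out = sum(brain))
  ir <- simulate_mri(ph, "ir_t1", noise_sd = 0)
  fit <- fit_t1(ir, mask = brain)
  rel <- abs(fit$t1$values[brain] / ph$truth_t1[brain] - 1)
  expect_lt(max(rel), 1e-3)
  expect_lt(max(abs(fit$m0$values[brain] / 100 - 1)), 1e-3)
  expect_lt(max(abs(fit$kappa$values[brain] - 1)), 1e-3)
})

test_that("flat voxel series are flagged non-converged", {
  series <- array(0, c(2, 2, 1, 18))
  series[1, 1, 1, ] <- 5            # constant: no recovery information
  tis <- exp(seq(log(0.03), log(10), length.out = 18))
  fit <- fit_t1(series, tis)
  expect_false(fit$converged[1, 1, 1])
  expect_true(all(is.na(fit$t1$values[!fit$converged])))
})

test_that("noisy T1 estimates stay accurate in the median", {
  ph <- make_phantom(dim = c(24, 24, 2))
  brain <- ph$label_map > 0
  ir <- simulate_mri(ph, "ir_t1", noise_sd = 2, seed = 6)  # 2% of M0
  fit <- fit_t1(ir, mask = brain)
  err <- abs(fit$t1$values[brain & fit$converged] / 1.7 - 1)
  expect_lt(stats::median(err), 0.03)
})

test_that("inversion efficiency follows its definition and limits", {
  ctrl <- matrix(100, 4, 4); mask <- matrix(TRUE, 4, 4)
  expect_equal(inversion_efficiency(ctrl, -ctrl, mask), 1)
  expect_error(inversion_efficiency(ctrl, ctrl, mask), "no inversion")
  expect_error(inversion_efficiency(ctrl * 0, ctrl, mask), "zero control")
  # alpha 0.85 with 1% noise recovered within 2%
  alpha <- 0.85
  # flow-compensated signed label signal: 100 (1 - 2 alpha) = -70
  lbl <- withr::with_seed(4, matrix(100 * (1 - 2 * alpha), 4, 4) +
                            rnorm(16, sd = 1))
  expect_equal(inversion_efficiency(ctrl, lbl, mask), alpha, tolerance = 0.02)
})

test_that("pCASL quantification inverts the single-compartment model", {
  ph <- make_phantom(dim = c(12, 12, 2),
                     values = list(cbf = c(contra = 81.21, ipsi = 50.68),
                                   bvf = c(contra = 3.73, ipsi = 3.18),
                                   adc = c(contra = 1e-3, ipsi = 1e-3),
                                   t1 = c(contra = 1.7, ipsi = 1.7),
                                   enhancement = c(contra = 0, ipsi = 0,
                                                   core = 30)))
  masks <- phantom_masks(ph)
  asl <- simulate_mri(ph, "pcasl", noise_sd = 0)
  cbf <- quantify_cbf(asl, t1_map = asl$t1, m0_map = asl$m0,
                      alpha = asl$params$alpha, mask = masks$brain)
  expect_equal(extract_roi(cbf, masks$contra)$mean, 81.21, tolerance = 1e-3)
  expect_equal(extract_roi(cbf, masks$ipsi)$mean, 50.68, tolerance = 1e-3)
  # the striatal headline: 38% reduction from these group means
  rc <- relative_change(extract_roi(cbf, masks$ipsi)$mean,
                        extract_roi(cbf, masks$contra)$mean)
  expect_equal(rc$rounded, 38L)

  # zero label effect -> zero flow
  asl0 <- asl; asl0$label <- asl0$control
  cbf0 <- quantify_cbf(asl0, asl$t1, asl$m0, mask = masks$brain)
  expect_true(all(cbf0$values[masks$brain] == 0))
})

test_that("CBF scales linearly with dM and inversely with alpha", {
  ph <- make_phantom(dim = c(8, 8, 1))
  masks <- phantom_masks(ph)
  asl <- simulate_mri(ph, "pcasl", noise_sd = 0)
  base <- quantify_cbf(asl, asl$t1, asl$m0, alpha = 0.8, mask = masks$brain)
  # doubling dM doubles CBF
  asl2 <- asl; asl2$label <- asl2$control - 2 * (asl$control - asl$label)
  dbl <- quantify_cbf(asl2, asl$t1, asl$m0, alpha = 0.8, mask = masks$brain)
  expect_equal(dbl$values[masks$brain], 2 * base$values[masks$brain],
               tolerance = 1e-12)
  # halving alpha doubles CBF
  half <- quantify_cbf(asl, asl$t1, asl$m0, alpha = 0.4, mask = masks$brain)
  expect_equal(half$values[masks$brain], 2 * base$values[masks$brain],
               tolerance = 1e-12)
})

test_that("delta-R2* blood volume quantification is exact on noiseless decays", {
  ph <- make_phantom(dim = c(10, 10, 1))
  masks <- phantom_masks(ph)
  mge <- simulate_mri(ph, "mge_pre_post", noise_sd = 0)
  bvf <- quantify_bvf(mge, mask = masks$brain)
  expect_equal(extract_roi(bvf, masks$contra)$mean, 3.9, tolerance = 1e-9)
  expect_equal(extract_roi(bvf, masks$ipsi)$mean, 3.4, tolerance = 1e-9)
  rc <- relative_change(3.4, 3.9)
  expect_equal(rc$rounded, 13L)

  # identical pre/post -> zero everywhere
  mge0 <- mge; mge0$post <- mge0$pre
  bvf0 <- quantify_bvf(mge0, mask = masks$brain)
  expect_true(all(bvf0$values[masks$brain] == 0))

  # log-linear fit against the closed form for one voxel
  tes <- mge$tes
  r2_pair <- c(28, 47.5)
  one <- list(pre = array(exp(-outer(1, tes) * r2_pair[1]) * 90,
                          c(1, 1, 1, 8)),
              post = array(exp(-outer(1, tes) * r2_pair[2]) * 90,
                           c(1, 1, 1, 8)),
              tes = tes)
  b1 <- quantify_bvf(one, mask = array(TRUE, c(1, 1, 1)))
  dr2s <- b1$provenance$dr2s[1]
  expect_equal(dr2s, diff(r2_pair), tolerance = 1e-10)

  # BVf is linear in dR2*: doubling delta_chi halves BVf
  k2 <- susceptibility_constants(delta_chi = 2e-7)
  b2 <- quantify_bvf(mge, constants = k2, mask = masks$brain)
  expect_equal(b2$values[masks$brain], bvf$values[masks$brain] / 2,
               tolerance = 1e-12)

  expect_error(quantify_bvf(list(pre = mge$pre, post = mge$post,
                                 tes = rev(tes))), "increasing")
})

test_that("negative dR2* voxels are clipped and flagged, not dropped", {
  tes <- 3.5e-3 + 5e-3 * (0:7)
  pre <- array(100 * exp(-tes * 40), c(1, 1, 1, 8))
  post <- array(100 * exp(-tes * 35), c(1, 1, 1, 8))   # R2* decreased
  b <- quantify_bvf(list(pre = pre, post = post, tes = tes),
                    mask = array(TRUE, c(1, 1, 1)))
  expect_equal(b$values[1], 0)
  expect_true(b$provenance$clipped[1])
})

test_that("ADC tensor and direction-average modes agree on isotropic data", {
  ph <- make_phantom(dim = c(8, 8, 1))
  masks <- phantom_masks(ph)
  dwi <- simulate_mri(ph, "dwi", noise_sd = 0)
  a_t <- quantify_adc(dwi, mode = "tensor", mask = masks$brain)
  a_m <- quantify_adc(dwi, mode = "mean", mask = masks$brain)
  expect_equal(a_t$values[masks$brain], rep(1e-3, sum(masks$brain)),
               tolerance = 1e-9)
  expect_equal(a_t$values[masks$brain], a_m$values[masks$brain],
               tolerance = 1e-12)
})

test_that("tensor-mode ADC recovers the trace of an anisotropic tensor", {
  D <- diag(c(2, 1, 0) * 1e-3)
  g <- dwi_directions(30)
  b <- 1000
  s0 <- 100
  adcs <- vapply(seq_len(nrow(g)), function(i) {
    exp(-b * drop(g[i, ] %*% D %*% g[i, ]))
  }, numeric(1)) * s0
  dwi <- list(b0 = array(s0, c(1, 1, 1)),
              dwi = array(adcs, c(1, 1, 1, 30)),
              bval = b, directions = g)
  a <- quantify_adc(dwi, mode = "tensor")
  expect_equal(a$values[1], 1e-3, tolerance = 1e-6)
  expect_error(quantify_adc(list(b0 = dwi$b0, dwi = dwi$dwi[, , , 1:4,
                                                            drop = FALSE],
                                 bval = b, directions = g[1:4, ]),
                            mode = "tensor"), "6 non-collinear")
})

test_that("gadolinium enhancement and opened-volume delineation work end to end", {
  ph <- make_phantom(dim = c(16, 16, 2))
  masks <- phantom_masks(ph)
  t1w <- simulate_mri(ph, "t1w_pre_post_gd", noise_sd = 0)
  gd <- gd_enhancement(t1w$pre, t1w$post, roi = masks$ipsi,
                       ref_mask = masks$contra, voxel_size = ph$voxel_size)
  expect_equal(gd$mean_enhancement, 18.66, tolerance = 1e-9)
  expect_identical(gd$opened_mask, masks$core)
  expect_equal(gd$opened_volume_mm3, sum(masks$core) * prod(ph$voxel_size))
  # the opened core occupies 5% of the treated ROI (up to voxel rounding)
  expect_lt(abs(sum(gd$opened_mask) / sum(masks$ipsi) - 0.05), 0.005)

  # no contrast leak
  gd0 <- gd_enhancement(t1w$pre, t1w$pre, masks$ipsi, masks$contra)
  expect_equal(gd0$opened_volume_mm3, 0)
  expect_true(all(gd0$enhancement$values[masks$brain] == 0))

  # delineation invariant to global intensity scaling
  gs <- gd_enhancement(t1w$pre * 3.7, t1w$post * 3.7, masks$ipsi, masks$contra)
  expect_identical(gs$opened_mask, gd$opened_mask)
  expect_equal(gs$mean_enhancement, gd$mean_enhancement, tolerance = 1e-12)

  expect_error(gd_enhancement(t1w$pre * 0, t1w$post, masks$ipsi, masks$contra),
               "zero pre")
})

test_that("pressure derating and mechanical index follow their closed forms", {
  expect_equal(mechanical_index(0.6, 1.5), 0.6 / sqrt(1.5))
  expect_equal(round(mechanical_index(0.6, 1.5), 1), 0.5)
  expect_equal(derate_pressure(0.8, 1.5, 0), 0.8)         # zero depth
  expect_equal(derate_pressure(1, 1.5, 0.005, alpha_brain = 5),
               exp(-0.0375))
  expect_equal(derate_pressure(1, 1.5, 0.005, skull_transmission = 0.5),
               0.5 * exp(-0.0375))
  expect_error(derate_pressure(1, 1.5, -1), "depth")
})

test_that("Rician noise is applied at magnitude level and is seeded", {
  ph <- make_phantom(dim = c(8, 8, 1))
  d1 <- simulate_mri(ph, "dwi", noise_sd = 1, seed = 3)
  d2 <- simulate_mri(ph, "dwi", noise_sd = 1, seed = 3)
  expect_identical(d1$dwi, d2$dwi)
  expect_true(all(d1$dwi >= 0))        # magnitude data
  d3 <- simulate_mri(ph, "dwi", noise_sd = 1, seed = 4)
  expect_false(identical(d1$dwi, d3$dwi))
  expect_error(simulate_mri(ph, "dwi", noise_sd = -1), "noise_sd")
  expect_error(simulate_mri(ph, "nope"), "arg")
})
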