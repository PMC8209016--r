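# MRI quantification: interpolation, thresholds, volumetry, pipeline

test_that("in-plane interpolation reaches the target grid and preserves extent", {
  v <- volume_image(array(rnorm(128 * 128 * 8), c(128, 128, 8)),
                    c(0.117, 0.117, 0.28), "T2STAR")
  vi <- interpolate_inplane(v, c(256, 256))
  expect_equal(dim(vi$intensities), c(256, 256, 8))
  expect_equal(vi$spacing, c(0.117 / 2, 0.117 / 2, 0.28))
  expect_equal(dim(vi$intensities)[1] * vi$spacing[1], 128 * 0.117)
  expect_error(interpolate_inplane(vi, c(128, 128)), "downsample")
})

test_that("interpolation reproduces constants and affine ramps", {
  cst <- volume_image(array(7, c(40, 40, 3)), c(1, 1, 1), "T2STAR")
  ci <- interpolate_inplane(cst, c(97, 81))
  expect_equal(range(ci$intensities), c(7, 7))
  ramp <- outer(seq_len(40), seq_len(40), function(i, j) 2 * i - 3 * j + 5)
  v <- volume_image(array(ramp, c(40, 40, 2)), c(1, 1, 1), "T2STAR")
  vi <- interpolate_inplane(v, c(120, 120))
  # interpolated values must lie on the same affine surface
  si <- 1 + (seq_len(120) - 1) * 39 / 119
  expected <- outer(si, si, function(i, j) 2 * i - 3 * j + 5)
  expect_lt(max(abs(vi$intensities[, , 1] - expected)), 1e-9 * diff(range(ramp)))
})

test_that("mask volume is voxel count times voxel volume", {
  m <- mask3d(array(c(rep(TRUE, 1000), rep(FALSE, 24)), c(32, 32, 1)),
              c(0.117, 0.117, 0.28), "LV")
  expect_equal(mask_volume(m), 1000 * 0.117 * 0.117 * 0.28, tolerance = 1e-12)
  expect_equal(mask_volume(mask3d(array(FALSE, c(4, 4, 4)), c(1, 1, 1), "LV")), 0)
  expect_equal(mask_volume(mask3d(array(TRUE, c(10, 10, 10)), c(1, 1, 1), "LV")), 1000)
})

test_that("T2* segmentation selects the signal-void band within the LV", {
  lv <- mask_all(4)
  expect_equal(sum(segment_reperfusion_t2star(vol3(rep(5, 4)), lv)$voxels), 0)
  bin <- segment_reperfusion_t2star(vol3(c(0, 1, 0, 1)), lv)
  expect_equal(as.vector(bin$voxels), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(segment_reperfusion_t2star(vol3(1:4), mask3d(array(FALSE, c(4, 1, 1)), c(1, 1, 1), "LV")), "empty")
  expect_error(segment_reperfusion_t2star(vol3(1:4), mask_all(5)), "mismatch")
})

test_that("T1 segmentation squares intensities so signed enhancement is caught", {
  lv <- mask_all(3); rep_m <- mask_all(3, label = "REPERFUSION")
  v <- vol3(c(-10, 0, 1), contrast = "T1IR")
  m <- segment_infarct_t1(v, lv, rep_m)          # squared {100, 0, 1}, thr 10
  expect_equal(as.vector(m$voxels), c(TRUE, FALSE, FALSE))
  one <- vol3(c(0, 0, 3), contrast = "T1IR")
  expect_equal(as.vector(segment_infarct_t1(one, lv, rep_m)$voxels),
               c(FALSE, FALSE, TRUE))
  expect_error(segment_infarct_t1(vol3(c(0, 0, 0), contrast = "T1IR"), lv, rep_m),
               "threshold undefined")
})

test_that("segmentation is invariant to global positive rescaling", {
  ph <- tiny_phantom(f = 0.5, snr = 20, seed = 3)
  a <- segment_reperfusion_t2star(ph$t2star, ph$lv_mask)
  sc <- volume_image(ph$t2star$intensities * 37.5, ph$t2star$spacing, "T2STAR")
  b <- segment_reperfusion_t2star(sc, ph$lv_mask)
  expect_identical(a$voxels, b$voxels)
  ia <- segment_infarct_t1(ph$t1ir, ph$lv_mask, a)
  sc1 <- volume_image(ph$t1ir$intensities * 4.2, ph$t1ir$spacing, "T1IR")
  expect_identical(segment_infarct_t1(sc1, ph$lv_mask, a)$voxels, ia$voxels)
})

test_that("raising the T1 fraction never grows the infarct mask", {
  ph <- tiny_phantom(f = 0.6, snr = 20, seed = 7)
  rep_m <- segment_reperfusion_t2star(ph$t2star, ph$lv_mask)
  prev <- NULL
  for (f in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    m <- segment_infarct_t1(ph$t1ir, ph$lv_mask, rep_m, fraction = f)
    if (!is.null(prev)) expect_false(any(m$voxels & !prev))
    prev <- m$voxels
  }
})

test_that("volumetry mirrors the 74/26 split and handles degenerate masks", {
  vox <- array(FALSE, c(20, 10, 1))
  lv <- vox; lv[1:200] <- TRUE
  rep_m <- vox; rep_m[1:100] <- TRUE
  inf <- vox; inf[1:74] <- TRUE
  r <- compute_volumetry(mask3d(lv, c(1, 1, 1), "LV"),
                         mask3d(rep_m, c(1, 1, 1), "REPERFUSION"),
                         mask3d(inf, c(1, 1, 1), "INFARCT"))
  expect_equal(r$infarct_pct_of_reperfusion, 74)
  expect_equal(r$salvage_pct_of_reperfusion, 26)
  expect_equal(r$infarct_pct_of_reperfusion + r$salvage_pct_of_reperfusion, 100)
  # infarct == reperfusion -> zero salvage; empty infarct -> full salvage
  r2 <- compute_volumetry(mask3d(lv, c(1, 1, 1), "LV"),
                          mask3d(rep_m, c(1, 1, 1), "REPERFUSION"),
                          mask3d(rep_m, c(1, 1, 1), "INFARCT"))
  expect_equal(r2$salvage_volume, 0); expect_equal(r2$salvage_pct_of_reperfusion, 0)
  r3 <- compute_volumetry(mask3d(lv, c(1, 1, 1), "LV"),
                          mask3d(rep_m, c(1, 1, 1), "REPERFUSION"),
                          mask3d(vox, c(1, 1, 1), "INFARCT"))
  expect_equal(r3$salvage_pct_of_reperfusion, 100)
  # containment violation and undefined normalization
  expect_error(compute_volumetry(mask3d(rep_m, c(1, 1, 1), "LV"),
                                 mask3d(lv, c(1, 1, 1), "REPERFUSION"),
                                 mask3d(inf, c(1, 1, 1), "INFARCT")), "containment")
  r4 <- compute_volumetry(mask3d(lv, c(1, 1, 1), "LV"),
                          mask3d(vox, c(1, 1, 1), "REPERFUSION"),
                          mask3d(vox, c(1, 1, 1), "INFARCT"))
  expect_true(is.na(r4$infarct_pct_of_reperfusion))
})

test_that("noise-free pipeline recovers the planted fraction to quantization", {
  ph <- tiny_phantom(f = 0.54, snr = Inf, seed = 1)
  out <- run_mri_pipeline(ph$t2star, ph$t1ir, ph$lv_mask,
                          config = list(target_inplane = c(64, 64)))
  expect_lt(abs(out$result$infarct_pct_of_reperfusion -
                100 * ph$truth$infarct_fraction), 1.5)
  cnt <- attr(out$result, "voxel_counts")
  expect_identical(cnt[["salvage"]] + cnt[["infarct"]], cnt[["reperfusion"]])
})

test_that("pipeline output respects the containment chain across seeds", {
  for (s in 1:3) {
    ph <- tiny_phantom(f = 0.4, snr = 20, seed = s)
    out <- run_mri_pipeline(ph$t2star, ph$t1ir, ph$lv_mask,
                            config = list(target_inplane = c(64, 64)))
    m <- out$masks
    expect_false(any(m$infarct$voxels & !m$reperfusion$voxels))
    expect_false(any(m$reperfusion$voxels & !m$lv$voxels))
  }
})

test_that("dice coefficient behaves at the boundaries", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(a & FALSE, b & FALSE), 1)
})
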