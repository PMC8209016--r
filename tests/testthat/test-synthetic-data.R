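# generators: truth invariants, determinism, planted-value exactness

test_that("phantom truth satisfies containment and hits the requested fraction", {
  for (f in c(0, 0.26, 0.5, 0.74, 1)) {
    ph <- tiny_phantom(f = f)
    tr <- ph$truth
    expect_false(any(tr$infarct_mask & !tr$reperfusion_mask))
    expect_false(any(tr$reperfusion_mask & !tr$lv_mask))
    n_rep <- sum(tr$reperfusion_mask)
    expect_lte(abs(sum(tr$infarct_mask) / n_rep - f), 1 / n_rep)  # one-voxel quantization
    expect_equal(tr$infarct_fraction, sum(tr$infarct_mask) / n_rep)
  }
})

test_that("phantom is bit-reproducible under a fixed seed and differs across seeds", {
  a <- tiny_phantom(snr = 20, seed = 11)
  b <- tiny_phantom(snr = 20, seed = 11)
  c <- tiny_phantom(snr = 20, seed = 12)
  expect_identical(a$t2star$intensities, b$t2star$intensities)
  expect_identical(a$t1ir$intensities, b$t1ir$intensities)
  expect_false(identical(a$t2star$intensities, c$t2star$intensities))
})

test_that("phantom rejects bad geometry and fractions", {
  expect_error(generate_cardiac_phantom(infarct_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generate_cardiac_phantom(grid_shape = c(16, 16, 4)), "geometry")
  expect_error(tiny_phantom(wedge_angle = -10), "geometry")
})

test_that("requested SNR 20 is realized empirically across seeded phantoms", {
  snr <- vapply(1:50, function(s) {
    ph <- generate_cardiac_phantom(grid_shape = c(48L, 48L, 8L), snr = 20, seed = s)
    phantom_empirical_snr(ph$t2star, ph$truth)
  }, numeric(1))
  expect_gte(mean(snr), 18)
  expect_lte(mean(snr), 22)
  expect_true(all(snr > 16 & snr < 24))
})

test_that("NMR cohort plants fold changes exactly in the design means", {
  coh <- generate_nmr_cohort(n_per_group = 2, seed = 4)
  pf <- coh$truth$planted_fold_changes
  dm <- coh$truth$design_means
  expect_equal(unname(dm["vehicle_IR", ] / dm["vehicle_sham", ]),
               pf$veh_IR_vs_sham)
  expect_equal(unname(dm["SCN_IR", ] / dm["SCN_sham", ]), pf$scn_IR_vs_sham)
  expect_equal(unname(dm["SCN_IR", ] / dm["vehicle_IR", ]), pf$scn_IR_vs_veh_IR)
  # the three highlighted sub-unity effects sit where expected
  expect_equal(pf$veh_IR_vs_sham[pf$name == "Phenylalanine"], 0.82)
  expect_gt(min(coh$truth$dilution_factors), 0)
})

test_that("null cohort without noise has identical group-mean spectra", {
  coh <- generate_nmr_cohort(n_per_group = 2, planted_folds = null_folds(),
                             conc_cv = 0, dilution_sd = 0, noise_sd = 0,
                             water_amplitude = 0, seed = 3)
  mats <- vapply(coh$spectra, function(s) s$intensity,
                 numeric(length(coh$spectra[[1]]$intensity)))
  gm <- sapply(split(seq_len(ncol(mats)), coh$truth$group_labels),
               function(i) rowMeans(mats[, i, drop = FALSE]))
  expect_lt(max(apply(gm, 1, function(r) diff(range(r)))), 1e-9 * max(gm))
})

test_that("NMR generator is deterministic and validates its inputs", {
  a <- generate_nmr_cohort(n_per_group = 2, seed = 9)
  b <- generate_nmr_cohort(n_per_group = 2, seed = 9)
  expect_identical(a$spectra[[5]]$intensity, b$spectra[[5]]$intensity)
  expect_identical(a$truth$dilution_factors, b$truth$dilution_factors)
  expect_error(generate_nmr_cohort(n_per_group = 1), ">= 2")
  expect_error(generate_nmr_cohort(n_per_group = 2, peak_width_ppm = 0), "positive")
  bad <- metabolite_assignment("x", 9.9)
  expect_error(generate_nmr_cohort(n_per_group = 2, assignments = bad,
                                   planted_folds = data.frame(name = "x",
                                     veh_IR_vs_sham = 1, scn_IR_vs_sham = 1,
                                     scn_IR_vs_veh_IR = 1),
                                   ppm_range = c(-1, 9)), "outside")
})

test_that("histology generator realizes the planted fractions by construction", {
  tr <- section_truth(1200, 0.4, 0.25, 6.45)
  sec <- generate_histology_section(tr, image_shape = c(96, 96), seed = 2)
  px <- sec$fluorescence$pixels
  tissue <- px > 150
  expect_equal(100 * sum(px > 350) / sum(tissue), 40, tolerance = 0.01)
  seg <- segment_collagen(sec$trichrome)
  expect_equal(100 * sum(seg$collagen) / sum(seg$tissue), 25, tolerance = 0.5)
  # degenerate ends
  s0 <- generate_histology_section(section_truth(0, 0, 1), c(64, 64), seed = 1)
  expect_equal(sum(s0$fluorescence$pixels > 350), 0)
  seg0 <- segment_collagen(s0$trichrome)
  expect_equal(sum(seg0$collagen), sum(seg0$tissue))
})

test_that("section truth validates distance grid and fractions", {
  expect_error(section_truth(700, 0.5, 0.5), "fixed grid")
  expect_error(section_truth(600, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("echo generator honours sd = 0 and the determinism contract", {
  es0 <- generate_echo_series(sd = 0, n_per_group = 2, seed = 5)
  eff <- es0$truth$group_effects
  key <- paste(es0$records$group, es0$records$site, es0$records$timepoint)
  ekey <- paste(eff$group, eff$site, eff$timepoint)
  expect_equal(es0$records$lvs_mm, eff$lvs_mm[match(key, ekey)])
  a <- generate_echo_series(seed = 6); b <- generate_echo_series(seed = 6)
  expect_identical(a$records, b$records)
  bad <- default_echo_effects(); bad$lvs_mm[1] <- 9  # lvs > lvd
  expect_error(generate_echo_series(bad), "lvd > lvs")
})

test_that("standard-curve generator is linear and exact when noise is off", {
  sd0 <- generate_standard_curve_data(true_unknowns = c(110, 0), slope = 0.5,
                                      noise_cv = 0, seed = 1)
  expect_equal(sd0$unknowns$peak_area, c(55, 0))
  expect_equal(sd0$calibration$peak_area, 0.5 * sd0$calibration$concentration_um)
  expect_error(generate_standard_curve_data(true_unknowns = -5), ">= 0")
  a <- generate_standard_curve_data(seed = 2)
  b <- generate_standard_curve_data(seed = 2)
  expect_identical(a$calibration, b$calibration)
})

test_that("section cohort plants its distance decay and correlation structure", {
  sc <- generate_section_cohort(n_animals = 20, target_r = -0.5, seed = 8)
  expect_true(all(sc$distance_um %in% seq(0, 4800, 600)))
  expect_true(all(sc$true_positive_fraction >= 0 & sc$true_positive_fraction <= 1))
  fit <- stats::coef(stats::lm(true_positive_fraction ~ distance_um, sc))
  expect_lt(fit[2], 0)
  r <- stats::cor(sc$true_collagen_fraction, sc$true_positive_fraction)
  expect_lt(r, -0.3); expect_gt(r, -0.7)
})
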