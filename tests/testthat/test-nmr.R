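# NMR preprocessing, PQN, quantification, fold changes, heatmap

test_that("TSP referencing shifts the axis so the apex sits at 0.00", {
  ppm <- seq(-0.5, 2, by = 0.005)
  lor <- function(x0) 0.004^2 / ((ppm - x0)^2 + 0.004^2)
  s <- spectrum1d(ppm, 10 * lor(0.02) + lor(1.03))
  r <- reference_to_tsp(s)
  expect_equal(r$ppm[which.max(r$intensity)], 0)
  expect_identical(r$intensity, s$intensity)
  s0 <- spectrum1d(ppm, 10 * lor(0))
  expect_equal(reference_to_tsp(s0)$ppm, s0$ppm)
  flat <- spectrum1d(ppm, rep(1, length(ppm)))
  expect_error(reference_to_tsp(flat), "no detectable")
})

test_that("known mis-referencing offsets are recovered within one axis step", {
  coh <- generate_nmr_cohort(n_per_group = 2, ref_offset_ppm = 0.015, seed = 6)
  r <- reference_to_tsp(coh$spectra[[1]])
  shift <- r$ppm[1] - coh$spectra[[1]]$ppm[1]
  expect_lt(abs(shift - (-0.015)), 0.005 + 1e-12)
})

test_that("water truncation removes exactly the cut and out-of-domain points", {
  ppm <- seq(-2, 11, by = 0.01)
  s <- spectrum1d(ppm, seq_along(ppm))
  t <- truncate_water(s)
  expect_false(any(t$ppm >= 4.67 & t$ppm <= 4.98))
  expect_false(any(t$ppm < -1 | t$ppm > 10))
  removed <- sum((ppm >= 4.67 & ppm <= 4.98) | ppm < -1 | ppm > 10)
  expect_equal(length(t$ppm), length(ppm) - removed)
  expect_true(any(abs(t$ppm - 4.5) < 1e-9))   # 4.50 retained
})

test_that("PQN recovers a planted factor of two and rescales to a common level", {
  ppm <- seq(0.5, 3, by = 0.005)
  base <- 0.004^2 / ((ppm - 1.03)^2 + 0.004^2) + 0.004^2 / ((ppm - 2.46)^2 + 0.004^2)
  s1 <- spectrum1d(ppm, base, "a"); s2 <- spectrum1d(ppm, 2 * base, "b")
  out <- pqn_normalize(list(s1, s2))
  expect_equal(unname(out$dilution_factors[["b"]] / out$dilution_factors[["a"]]), 2)
  expect_equal(out$spectra[[1]]$intensity, out$spectra[[2]]$intensity)
  # identical spectra: equal factors, pure global rescale preserving ratios
  out2 <- pqn_normalize(list(s1, spectrum1d(ppm, base, "c")))
  expect_equal(unname(diff(out2$dilution_factors)), 0)
  i <- which.max(base)
  expect_equal(out2$spectra[[1]]$intensity / out2$spectra[[1]]$intensity[i],
               base / base[i])
  expect_error(pqn_normalize(list(spectrum1d(ppm, 0 * ppm), spectrum1d(ppm, 0 * ppm))),
               "all-zero")
  expect_error(pqn_normalize(list(s1)), "at least 2")
})

test_that("PQN recovers planted lognormal dilution on a small cohort", {
  coh <- generate_nmr_cohort(n_per_group = 4, planted_folds = null_folds(),
                             dilution_sd = 0.2, seed = 21)
  nrm <- pqn_normalize(preprocess_cohort(coh$spectra))
  est <- nrm$dilution_factors
  tru <- coh$truth$dilution_factors
  est <- est * stats::median(tru) / stats::median(est)  # factors defined up to scale
  expect_gt(stats::cor(est, tru), 0.99)
  expect_lt(stats::median(abs(est - tru) / tru), 0.02)
})

test_that("fixed-window quantification is linear and respects window isolation", {
  ppm <- seq(0.5, 2, by = 0.0005)
  g <- 0.004
  lor <- function(x0, A) A * g^2 / ((ppm - x0)^2 + g^2)
  s1 <- spectrum1d(ppm, lor(1.03, 1))
  s2 <- spectrum1d(ppm, lor(1.03, 2))
  asg <- metabolite_assignment("valine", 1.03, 0.02)
  expect_equal(quantify_metabolites(s2, asg)[["valine"]],
               2 * quantify_metabolites(s1, asg)[["valine"]])
  expect_equal(unname(quantify_metabolites(spectrum1d(ppm, 0 * ppm), asg)), 0)
  # two peaks 0.2 ppm apart: cross-talk below 1%, matching the closed form
  two <- spectrum1d(ppm, lor(1.0, 1) + lor(1.2, 1))
  asg2 <- metabolite_assignment(c("p1", "p2"), c(1.0, 1.2), 0.02)
  q <- quantify_metabolites(two, asg2)
  own <- g * 2 * atan(0.02 / g)                       # window integral, own peak
  tail <- g * (atan(0.22 / g) - atan(0.18 / g))       # neighbour leakage
  expect_equal(unname(q[["p1"]]), own + tail, tolerance = 0.01)
  expect_lt(tail / own, 0.01)
  # windows straddling the water cut shrink with a warning; empty ones error
  s3 <- spectrum1d(seq(4, 5.5, by = 0.005), rep(1, 301))
  expect_warning(quantify_metabolites(s3, metabolite_assignment("w", 4.66, 0.02)),
                 "water")
  expect_error(quantify_metabolites(s1, metabolite_assignment("out", 5, 0.001)),
               "empty")
})

test_that("fold-change table handles identity, halving, and arm validation", {
  q <- cbind(m1 = c(1, 2, 3, 1, 2, 3), m2 = c(2, 4, 6, 1, 2, 3))
  rownames(q) <- paste0("s", 1:6)
  des <- data.frame(sample_id = rownames(q),
                    group = rep(c("g1", "g2"), each = 3))
  cmp <- list(same = c("g1", "g1"), half = c("g2", "g1"))
  # identical arms: fold 1, t = 0, p = 1
  f <- fold_change_table(q, des, comparisons = list(same = c("g1", "g1")))
  expect_equal(f$fold_change, c(1, 1))
  expect_equal(f$p_value, c(1, 1))
  # g1 m2-column is exactly half the g2 m2-column
  f2 <- fold_change_table(q, des, comparisons = list(h = c("g2", "g2")))
  expect_equal(f2$fold_change, c(1, 1))
  q2 <- q; q2[4:6, ] <- 0.5 * q[1:3, ]
  f3 <- fold_change_table(q2, des, comparisons = list(h = c("g1", "g2")))
  expect_equal(f3$fold_change, c(0.5, 0.5))
  expect_error(fold_change_table(q[1:4, ], des[c(1, 2, 3, 4), ],
                                 comparisons = list(x = c("g1", "g2"))), ">= 2")
  expect_error(fold_change_table(q * 0, des, comparisons = list(x = c("g1", "g2"))),
               "zero mean")
})

test_that("preprocessing is order-stable around cohort normalization", {
  coh <- generate_nmr_cohort(n_per_group = 2, seed = 13)
  a <- pqn_normalize(lapply(coh$spectra, function(s) truncate_water(reference_to_tsp(s))))
  b <- pqn_normalize(lapply(coh$spectra, function(s) reference_to_tsp(truncate_water(s))))
  expect_equal(a$dilution_factors, b$dilution_factors)
  expect_equal(a$spectra[[3]]$intensity, b$spectra[[3]]$intensity)
})

test_that("heatmap matrix has table shape, shift order and fold orientation", {
  coh <- generate_nmr_cohort(n_per_group = 2, conc_cv = 0, dilution_sd = 0,
                             noise_sd = 0, seed = 2)
  qc <- quantify_cohort(preprocess_cohort(coh$spectra), serum_assignments())
  f <- fold_change_table(qc$quant, qc$design)
  hm <- heatmap_matrix(f)
  expect_equal(dim(hm), c(24L, 3L))
  expect_equal(rownames(hm)[1], "Formate")      # 8.52 ppm first
  expect_equal(rownames(hm)[24], "Lipids (LDL)")  # 0.87 ppm last
  # orientation: planted 1.15 lands above 1, planted 0.82 below
  expect_gt(hm["Glutamine", "scn_IR_vs_sham"], 1)
  expect_lt(hm["Phenylalanine", "veh_IR_vs_sham"], 1)
  # all-unity folds give a matrix at the centre value
  fu <- f; fu$fold_change <- 1
  expect_true(all(heatmap_matrix(fu) == 1))
})
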