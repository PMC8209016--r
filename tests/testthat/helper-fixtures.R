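# shared fixtures, built in code

# a tiny phantom configuration used where geometry, not recovery, is under test
tiny_phantom <- function(f = 0.5, snr = Inf, seed = 1L, ...) {
  generate_cardiac_phantom(grid_shape = c(32L, 32L, 6L),
                           infarct_fraction = f, snr = snr, seed = seed, ...)
}

# wrap a bare numeric vector as a 3-D volume along x
vol3 <- function(values, spacing = c(1, 1, 1), contrast = "T2STAR") {
  volume_image(array(values, c(length(values), 1, 1)), spacing, contrast)
}

mask_all <- function(n, spacing = c(1, 1, 1), label = "LV") {
  mask3d(array(TRUE, c(n, 1, 1)), spacing, label)
}

# truth masks carried onto an interpolated grid, for Dice against pipeline masks
truth_masks_on <- function(ph, target) {
  list(reperfusion = interpolate_mask_inplane(
         mask3d(ph$truth$reperfusion_mask, ph$t2star$spacing, "REPERFUSION"), target),
       infarct = interpolate_mask_inplane(
         mask3d(ph$truth$infarct_mask, ph$t2star$spacing, "INFARCT"), target))
}

# serum panel with planted folds all 1 (null cohort)
null_folds <- function() {
  f <- serum_fold_changes("24h")
  f$veh_IR_vs_sham <- f$scn_IR_vs_sham <- f$scn_IR_vs_veh_IR <- 1
  f
}

# standard NMR preprocessing chain
preprocess_cohort <- function(spectra) {
  lapply(spectra, function(s) truncate_water(reference_to_tsp(s)))
}
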