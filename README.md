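# irquant

Quantitative analysis of myocardial ischemia–reperfusion (IR) injury in
rodent cardioprotection studies, across five modalities in one R package:

* **MRI volumetry** — the reperfused territory is segmented on a T2\*
  magnitude volume as the iron-induced signal void (voxels at or below
  0.66 of the LV-masked maximum), the infarct on a signed T1
  inversion-recovery reconstruction by squared intensity (at or above 0.10
  of the LV-masked squared maximum), both clipped to the left-ventricle
  mask. Volumes are voxel counts times the voxel volume;
  `salvage = reperfusion − infarct` exactly, and all volumes are reported
  normalized (infarct and salvage as % of the reperfused volume, everything
  as % of LV).
* **Serum ¹H-NMR metabolomics** — TSP referencing to 0.00 ppm, −1.0..10.0
  ppm domain with the 4.67–4.98 ppm residual-water cut, probabilistic
  quotient normalization (median-spectrum reference, median quotient above
  a noise floor), fixed ±0.02 ppm window integration at the 24 assignment
  shifts of a built-in serum panel, fold changes as ratios of group means
  with two-tailed Welch tests, PCA, and OPLS-DA (1 predictive +
  n orthogonal components, leave-one-out Q², label-permutation p-value).
* **Histology** — fluorescence positivity with fixed grayscale thresholds
  (tissue > 150, positive > 350; `% positive = 100·|>350| / |>150|`),
  hue/saturation-rule collagen segmentation of trichrome images, areas in
  µm² at the stated µm/pixel, distance-to-ligation profiles over the fixed
  0–4800 µm grid, and the collagen-vs-oxidative-damage Pearson correlation.
* **Echo and serum SCN⁻** — fractional shortening
  `FS = 100·(LVd − LVs)/LVd`, per-site two-way ANOVA trajectory summaries
  with Dunnett/Sidak post-hocs, and thiocyanate quantification by inverse
  prediction from a 0–200 µM ion-chromatography standard curve.
* **Statistics** — Welch t, one-way ANOVA with the Newman-Keuls
  studentized-range ladder (Tukey alternative), two-way ANOVA (type-II SS)
  with Dunnett/Sidak, Pearson r.

Because studies of this design rarely deposit raw data, every module is
paired with a seeded synthetic-data generator carrying ground truth
(`generate_cardiac_phantom()`, `generate_nmr_cohort()`,
`generate_histology_section()`, `generate_echo_series()`,
`generate_standard_curve_data()`), and the test suite verifies the whole
pipeline by parameter recovery. See `vignettes/irquant-methods.Rmd` for the
models, assumptions and design decisions.

## Worked example

Generate a phantom with a planted infarct occupying 74% of the reperfusion
wedge at SNR 20, run the full MRI pipeline, and compare with truth:

```r
library(irquant)

ph <- generate_cardiac_phantom(infarct_fraction = 0.74, snr = 20, seed = 3)
out <- run_mri_pipeline(ph$t2star, ph$t1ir, ph$lv_mask,
                        config = list(target_inplane = c(128, 128)))
out$result
#> <volumetry_result> (mm^3)
#>   LV 958.118 | reperfusion 156.287 | infarct 114.512 | salvage 41.776
#>   infarct 73.3% / salvage 26.7% of reperfusion; reperfusion 16.3% of LV
100 * ph$truth$infarct_fraction
#> [1] 73.99194
```

The planted 74% infarct fraction is recovered at 73.3% (0.7 percentage
points of error at SNR 20), and salvage + infarct equals the reperfusion
volume exactly. The pipeline is deterministic per seed.

A serum cohort with the built-in planted fold changes, preprocessed,
normalized and tested:

```r
coh  <- generate_nmr_cohort(n_per_group = 8, seed = 1)
pre  <- lapply(coh$spectra, function(s) truncate_water(reference_to_tsp(s)))
norm <- pqn_normalize(pre)
qc   <- quantify_cohort(norm$spectra, serum_assignments())
ft   <- fold_change_table(qc$quant, qc$design)
subset(ft, metabolite == "Phenylalanine" & comparison == "veh_IR_vs_sham")
#>      metabolite     comparison fold_change      p_value significant
#> 5 Phenylalanine veh_IR_vs_sham   0.8274128 2.331088e-06        TRUE
```

The planted phenylalanine fold for IR vs sham in the vehicle arm is 0.82;
the estimate (0.827) lands within sampling noise of an n = 8/arm cohort at
5% CV, and the Welch test calls it significant.

## Command line

An `Rscript` entry point is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "irquant.R", package = "irquant"))')
Rscript "$CLI" simulate phantom --seed 1 --out-dir sim
Rscript "$CLI" mri --t2star sim/t2star.nii.gz --t1 sim/t1ir.nii.gz \
        --lv-mask sim/lv_mask.nii.gz --out-dir mri_out
Rscript "$CLI" report --seed 1 --out-dir study_out   # full synthetic study
```

All flags may also be given through one YAML file via `--config`.

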