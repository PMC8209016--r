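---
title: "Methods and design of the irquant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the irquant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irquant)
```

# Scope

`irquant` implements the quantitative analysis chain of a rodent
ischemia-reperfusion (IR) cardioprotection study across five modalities:
dual-contrast MRI volumetry of the infarct and salvageable myocardium, serum
^1^H-NMR metabolomics, threshold-based histology quantification,
echocardiographic indices, and thiocyanate (SCN^-^) quantification from
ion-chromatography standard curves. Because no raw animal data are available
for such a study design, every analysis module is paired with a seeded
synthetic-data generator that carries its ground truth, and the package's
correctness argument is *parameter recovery*: the generator plants known
quantities, the analysis modules must recover them within stated tolerances.

# MRI volumetry

## Model

The reperfused territory is delineated on a T2\* magnitude volume: iron
microparticles infused during reperfusion destroy T2\* signal, so the
territory appears as a signal void inside an otherwise bright left ventricle
(LV). The infarct core is delineated on a signed T1 inversion-recovery real
reconstruction, where gadolinium accumulation produces high-magnitude voxels
of either sign. The analysis chain is:

1. bilinear per-slice interpolation of both contrasts (and the LV mask) to a
   common finer in-plane grid (default 256 x 256), preserving the physical
   field of view;
2. reperfusion segmentation: LV voxels with intensity at or below
   `0.66 * max(intensity over the LV mask)`;
3. infarct segmentation: LV voxels whose *squared* intensity is at or above
   `0.10 * max(squared intensity over the LV mask)`, then intersected with
   the reperfusion mask;
4. volumetry: `|voxels| * dx*dy*dz` per mask;
   `salvage = reperfusion - infarct`, computed on voxel counts so the
   identity is exact; all volumes are normalized by LV volume and
   infarct/salvage additionally by reperfusion volume.

## Numerical and design choices

* **Threshold direction.** "From a minimum to a fraction of maximum" is
  direction-ambiguous in words; physically the iron territory is the *low*
  band on T2\* and gadolinium the *high* band after squaring, and that is
  the default. Both comparisons are config-overridable
  (`t2_direction`, `t1_square`, `t1_max_of`) because real reconstructions
  differ between scanners.
* **Maximum over the LV mask, not the field of view** — background
  artifacts outside the heart must not set the threshold.
* **Ties at the threshold are included** (`<=` / `>=`), fixed by test.
* **Infarct clipped to the reperfusion mask.** The LV-only clipping
  described for the original analysis presupposes containment; enforcing it
  guarantees salvage is never negative.
* **Interpolation is node-centred bilinear**, which reproduces affine
  intensity ramps exactly and never extrapolates; spacing is rescaled so
  the physical extent is unchanged. Downsampling is refused.

## The digital phantom

The phantom is the simplest geometry with the required containment
structure: a circular annulus (LV) per slice, an angular wedge spanning the
central slices (reperfusion), and the radially inner portion of the wedge
(infarct), sized to `round(f * N_wedge)` voxels so the planted
infarct-to-reperfusion fraction is honoured to one-voxel quantization. The
default grid spreads the 15/15/18 mm ex-vivo field of view over 64 x 64 x 16
voxels; tests interpolate 2x in-plane. This is deliberately smaller than the
full 128 x 128 x 64 acquisition matrix purely for runtime; the code path is
identical at any size.

Noise is Rician on the T2\* magnitude image, built as
`sqrt((S + n1)^2 + n2^2)` with Gaussian `n1, n2`, and additive Gaussian on
the signed T1-IR real reconstruction — a signed image cannot be Rician, and
keeping signed values is what exercises the squared-intensity step on
negative voxels. SNR is defined as bright-tissue amplitude over the Gaussian
sigma. The heart is embedded in a signal-bearing medium at 0.85 of the
bright-LV level, emulating agar embedding; this also prevents LV-rim partial
voluming from aliasing into the T2\* void band, a genuine artifact of
zero-signal backgrounds that the original ex-vivo protocol avoids the same
way. What a green phantom test does **not** establish: performance on
anatomically realistic hearts, motion, registration error between contrasts,
or manual delineation variability — the LV mask is an input by design.

# Serum NMR metabolomics

## Preprocessing

Spectra are referenced so the TSP apex sits at exactly 0.00 ppm (apex search
in a +/-0.2 ppm window), truncated to the -1.0..10.0 ppm working domain with
the 4.67-4.98 ppm residual-water band removed, and normalized by
probabilistic quotient normalization (PQN): the reference is the point-wise
median spectrum of the cohort, each sample's dilution factor is the median
quotient sample/reference over variables where the reference exceeds a noise
floor of 5x the baseline s.d. (MAD of the reference), and the spectrum is
divided by its factor. PQN factors are identifiable only up to one global
scale, so recovery against planted factors is measured after matching
medians. Preprocessing is order-stable: referencing and truncation commute
around cohort normalization, which the suite asserts.

## Quantification and inference

Named metabolites are quantified by trapezoidal integration over fixed
windows of +/-0.02 ppm (configurable) around the 24 assignment shifts of the
built-in serum panel (`serum_assignments()`, formate 8.52 ppm to LDL lipids
0.87 ppm). This replaces statistical-recoupling clustering with a
transparent primitive: integrals are linear in intensity, so the ratios that
fold changes need are preserved, and Lorentzian cross-talk between windows
separated by at least five linewidths is below 1% (closed-form tail
integral, asserted in tests). Because two panel pairs sit only 0.03 ppm
apart (creatinine/creatine at 3.03/3.00 and methylhistidine/histidine at
7.74/7.71), full +/-0.02 ppm windows would integrate each other's peaks;
adjacent windows are therefore clipped at the midpoint between their
shifts, so windows never overlap and residual mixing is tail leakage only
(a deterministic fold attenuation of about 1.5% in slope terms, quantified
from the exact Lorentzian mixing matrix). Absolute quantification is
explicitly out of scope.

Fold changes are ratios of group means with two-tailed Welch tests,
uncorrected per metabolite (the convention of the tables this mirrors);
Benjamini-Hochberg is available. PCA is mean-centred `prcomp`. OPLS-DA fits
one predictive component after deflating `n_orthogonal` orthogonal
components (NIPALS), scores models by leave-one-out Q^2^, and validates by
label permutation with `p = (1 + #[Q2_perm >= Q2_obs]) / (1 + B)`.

## The cohort generator

Each spectrum is a sum of Lorentzian peaks (half-width 0.004 ppm) at the
panel shifts on a 0.005 ppm grid, scaled by per-sample concentrations times
a lognormal dilution factor (sd 0.2), plus a TSP reference peak (an internal
standard, hence *not* dilution-scaled), a broad residual-water bump, and
Gaussian baseline noise. Group design means encode the planted fold-change
table exactly; per-sample concentrations are mean-preserving lognormal with
CV 5% by default — the within-group spread a serum panel at n = 8/arm
plausibly shows. Two consequences the tests account for:

* **Dilution-recovery runs use a null cohort** (all planted folds 1). With
  group effects present, a sample's PQN factor correctly absorbs its group's
  common-mode concentration shift, so comparing factors to planted *pure
  dilution* would confound two true quantities; the null cohort isolates the one
  under test.
* **Fold-change recovery is an operating characteristic.** A single cohort
  at n = 8/arm, CV 5% carries irreducible sampling noise of about 2.5% per
  fold — a realized cohort's regression slope scatters around 1 by ~0.05 no
  matter how good the analysis is. The acceptance measurement therefore
  averages slope and recovered folds over 20 replicate cohorts, which
  estimates the pipeline's expected recovery rather than one draw's luck.
  PQN also compresses all folds of a comparison toward 1 by the group's
  median planted fold (~2% here) — an intrinsic, documented property of
  quotient normalization, visible as a small common offset, not a slope
  change.

# Histology

Fluorescence sections are quantified with the fixed grayscale thresholds
150 (background/tissue) and 350 (positivity), strict `>` per their "over
150 / over 350" definition, on raw stored values with no prior
normalization; mean intensity is over tissue pixels only (tissue-only is a
documented choice where the convention is unstated). Collagen is segmented
from trichrome RGB images with an explicit hue-saturation rule (tissue =
saturation >= 0.15; collagen = hue 150-300 degrees) replacing a proprietary
trained classifier; the rule is exact on synthetic stains and tunable for
real ones. Areas follow `|pixels| * (um/pixel)^2` at the native resolutions
(4.4 um/px brightfield, 6.45 um/px fluorescence). Distance profiles
aggregate mean +/- SEM over the fixed 0-4800 um sectioning grid and flag —
never impute — missing distances. The collagen-oxidation association is a
Pearson correlation, pooled and per animal.

The section generator plants exact pixel-count fractions (positives and
collagen as seeded random subsets of the tissue disk), so noise-free
round-trips are exact to quantization; the cohort generator plants a linear
distance decay of positivity and a target correlation between collagen and
positivity through a shared latent term (population value, before clamping
fractions to [0.02, 0.98]).

# Echocardiography and SCN^-^

Fractional shortening is `100 * (LVd - LVs) / LVd`. Trajectories are
summarized as mean +/- SEM (sample s.d. over sqrt(n)) per group, site and
timepoint, with a per-site two-way ANOVA (group x timepoint, type-II sums of
squares, which reduce to the classical decomposition on balanced layouts)
and Dunnett many-to-one or Sidak post-hocs computed from the full-model
mean-square error within each timepoint. Physiologically impossible records
(LVs > LVd) are flagged, never dropped. SCN^-^ is quantified by inverse
prediction from an OLS standard curve over 0-200 uM; curves with r^2^ < 0.99
warn, negative predictions clamp to zero with a warning.

# Statistics module

Welch's t (with Welch-Satterthwaite df), one-way ANOVA with the
Newman-Keuls stepwise studentized-range ladder (retained stretches block
inner pairs), Pearson r with the t-transform p-value, and the two-way ANOVA
above are implemented directly and cross-checked in the suite against base R
oracles; Dunnett adjusted p-values use the multivariate-t integral with the
`sqrt(lambda_i lambda_j)` correlation structure (via mvtnorm, pinned to a
fixed quasi-MC seed so identical inputs give identical p-values).
Newman-Keuls is provided because the mirrored study design uses it, with
Tukey HSD available as the non-liberal alternative; its known liberality is
inherited knowingly. Significance is fixed at p < 0.05 throughout.

# Determinism

Every generator takes a required seed and routes all randomness through a
scoped RNG that restores the caller's stream, so generators are pure
functions of their arguments. `run_synthetic_study()` derives module
sub-seeds from one master seed and produces byte-identical CSV/JSON/MD
outputs on reruns (PDF figures embed a creation date and are excluded from
the byte-identity contract).

# Known limitations

* Phantoms validate the segmentation arithmetic, not anatomical realism;
  there is no k-space simulation, relaxometry, or registration.
* NMR starts from processed real spectra; FID processing (line broadening,
  Fourier transform, phasing) is out of scope.
* Fixed-window integration is a deliberate simplification of
  statistical-recoupling quantification; only ratio-scale conclusions are
  supported.
* The collagen colour rule is not a substitute for a trained classifier on
  real slides with stain variability.
* Dunnett p-values assume the balanced correlation structure; mildly
  unbalanced designs use the harmonic approximation inherent in
  `n_i/(n_i + n0)`.
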