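#' Simulate a serum 1H-NMR cohort with planted fold changes
#'
#' Generates one spectrum per sample for the four-group design
#' (`vehicle_sham`, `vehicle_IR`, `SCN_sham`, `SCN_IR`). Each spectrum is a
#' sum of Lorentzian peaks at the assignment shifts, with per-sample true
#' metabolite concentrations drawn around group means that encode the
#' planted fold changes, multiplied by a per-sample lognormal dilution
#' factor, plus a TSP reference peak at 0.00 ppm (internal standard, not
#' dilution-scaled), a broad residual-water bump inside 4.67-4.98 ppm, and
#' additive Gaussian baseline noise.
#'
#' Group means are constructed so every planted comparison is honoured
#' exactly: `vehicle_IR = base * f_veh`, `SCN_IR = vehicle_IR * f_cross`,
#' `SCN_sham = SCN_IR / f_scn`, where the three `f` columns are
#' IR-vs-sham (vehicle), IR-vs-sham (SCN) and SCN/IR-vs-vehicle/IR folds.
#' Per-sample concentrations are mean-preserving lognormal:
#' `mean * exp(cv * z - cv^2 / 2)`.
#'
#' @param n_per_group samples per group (>= 2).
#' @param assignments [metabolite_assignment()] table; default the built-in
#'   24-metabolite serum panel.
#' @param planted_folds data.frame with columns `name`, `veh_IR_vs_sham`,
#'   `scn_IR_vs_sham`, `scn_IR_vs_veh_IR` (default [serum_fold_changes()]
#'   at 24 h); row order must match `assignments`.
#' @param peak_width_ppm Lorentzian half-width at half-maximum (ppm).
#' @param conc_cv within-group coefficient of variation of true
#'   concentrations.
#' @param dilution_sd s.d. of log dilution factors (`exp(rnorm(0, sd))`).
#' @param noise_sd additive baseline noise s.d. (intensity units).
#' @param water_amplitude amplitude of the residual-water bump.
#' @param ref_offset_ppm global mis-referencing offset applied to the ppm
#'   axis (recovered downstream by TSP referencing).
#' @param ppm_range,ppm_step spectral axis; defaults -1.0..10.0 ppm at
#'   0.005 ppm resolution.
#' @param timepoint label stored on each spectrum.
#' @param seed integer seed.
#' @return list with `spectra` (list of [spectrum1d()]) and `truth`
#'   (`cohort_truth`: `group_labels`, `metabolite_concentrations` matrix,
#'   `design_means` group-by-metabolite matrix, `planted_fold_changes`,
#'   `dilution_factors`, `seed`).
#' @export
generate_nmr_cohort <- function(n_per_group = 8L,
                                assignments = serum_assignments(),
                                planted_folds = serum_fold_changes("24h"),
                                peak_width_ppm = 0.004,
                                conc_cv = 0.05,
                                dilution_sd = 0.2,
                                noise_sd = 0.02,
                                water_amplitude = 40,
                                ref_offset_ppm = 0,
                                ppm_range = c(-1, 10),
                                ppm_step = 0.005,
                                timepoint = "24h",
                                seed = 1L) {
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2")
  if (peak_width_ppm <= 0) stop("peak width must be positive")
  if (any(assignments$shift_ppm < ppm_range[1] | assignments$shift_ppm > ppm_range[2]))
    stop("assignment shift outside the spectral range")
  if (dilution_sd < 0 || conc_cv < 0 || noise_sd < 0) stop("spread parameters must be >= 0")
  stopifnot(nrow(planted_folds) == nrow(assignments))

  groups <- c("vehicle_sham", "vehicle_IR", "SCN_sham", "SCN_IR")
  m <- nrow(assignments)
  ppm <- seq(ppm_range[1], ppm_range[2], by = ppm_step)

  out <- with_seed(seed, {
    base <- stats::runif(m, 50, 150)           # vehicle/sham design means
    f1 <- planted_folds$veh_IR_vs_sham
    f2 <- planted_folds$scn_IR_vs_sham
    f3 <- planted_folds$scn_IR_vs_veh_IR
    design <- rbind(vehicle_sham = base,
                    vehicle_IR   = base * f1,
                    SCN_IR       = base * f1 * f3,
                    SCN_sham     = base * f1 * f3 / f2)[groups, , drop = FALSE]
    colnames(design) <- assignments$name

    n <- 4L * n_per_group
    glab <- rep(groups, each = n_per_group)
    conc <- matrix(NA_real_, n, m, dimnames = list(NULL, assignments$name))
    for (i in seq_len(n)) {
      mu <- design[glab[i], ]
      z <- stats::rnorm(m)
      conc[i, ] <- mu * exp(conc_cv * z - conc_cv^2 / 2)
    }
    dil <- exp(stats::rnorm(n, 0, dilution_sd))
    water_amp <- water_amplitude * stats::runif(n, 0.6, 1.4)

    g2 <- peak_width_ppm^2
    # Lorentzian basis: rows = axis points, cols = metabolites
    basis <- vapply(assignments$shift_ppm,
                    function(x0) g2 / ((ppm - x0)^2 + g2), numeric(length(ppm)))
    tsp <- 80 * g2 / (ppm^2 + g2)
    water <- exp(-0.5 * ((ppm - 4.82) / 0.05)^2)

    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      sig <- dil[i] * drop(basis %*% conc[i, ]) + tsp +
        water_amp[i] * water +
        if (noise_sd > 0) stats::rnorm(length(ppm), 0, noise_sd) else 0
      spectra[[i]] <- spectrum1d(ppm + ref_offset_ppm, sig,
                                 sample_id = sprintf("S%02d", i),
                                 group = glab[i], timepoint = timepoint)
    }
    list(spectra = spectra, conc = conc, dil = dil, design = design, glab = glab)
  })

  truth <- structure(list(
    group_labels = out$glab,
    metabolite_concentrations = out$conc,
    design_means = out$design,
    planted_fold_changes = planted_folds,
    dilution_factors = out$dil,
    seed = seed), class = "cohort_truth")
  list(spectra = out$spectra, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d samples, %d metabolites, dilution sd(log) %.3f, seed %s\n",
              length(x$group_labels), ncol(x$metabolite_concentrations),
              stats::sd(log(x$dilution_factors)), format(x$seed)))
  invisible(x)
}
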