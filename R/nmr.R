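# Serum 1H-NMR processing chain: TSP referencing, water truncation,
# probabilistic quotient normalization, fixed-window quantification at the
# assignment shifts, and Welch fold-change tables.

#' Reference a spectrum to the TSP peak
#'
#' Shifts the ppm axis so the apex of the TSP resonance (sought inside
#' `search_window`) sits at exactly 0.00 ppm. Intensities are untouched.
#'
#' @param spec a [spectrum1d()].
#' @param search_window ppm interval searched for the TSP apex.
#' @return referenced `spectrum1d`.
#' @export
reference_to_tsp <- function(spec, search_window = c(-0.2, 0.2)) {
  stopifnot(inherits(spec, "spectrum1d"))
  win <- spec$ppm >= search_window[1] & spec$ppm <= search_window[2]
  if (!any(win)) stop("no spectral points inside the TSP search window")
  y <- spec$intensity[win]
  if (max(y) - min(y) <= 1e-12 * max(1, abs(max(y))))
    stop("no detectable TSP peak inside the search window")
  apex <- spec$ppm[win][which.max(y)]
  spectrum1d(spec$ppm - apex, spec$intensity, spec$sample_id, spec$group, spec$timepoint)
}

#' Truncate the residual water signal and restrict the spectral domain
#'
#' Removes all points with ppm inside the water cut (default 4.67-4.98 ppm,
#' inclusive) and outside the working domain (default -1.0..10.0 ppm).
#'
#' @param spec a [spectrum1d()].
#' @param cut ppm interval to remove.
#' @param domain ppm interval to keep.
#' @return truncated `spectrum1d`.
#' @export
truncate_water <- function(spec, cut = c(4.67, 4.98), domain = c(-1, 10)) {
  stopifnot(inherits(spec, "spectrum1d"))
  keep <- !(spec$ppm >= cut[1] & spec$ppm <= cut[2]) &
    spec$ppm >= domain[1] & spec$ppm <= domain[2]
  if (sum(keep) < 2L) stop("truncation leaves fewer than 2 points")
  spectrum1d(spec$ppm[keep], spec$intensity[keep],
             spec$sample_id, spec$group, spec$timepoint)
}

#' Probabilistic quotient normalization of a spectral cohort
#'
#' The reference is the point-wise median spectrum across the cohort. Each
#' sample's dilution factor is the median, over spectral variables where the
#' reference exceeds a noise floor, of the quotient sample/reference; each
#' spectrum is divided by its factor. The noise floor is
#' `noise_floor_k` times the baseline s.d. of the reference, estimated by
#' the median absolute deviation around the reference median (baseline
#' points dominate a 1-D serum spectrum).
#'
#' @param cohort list of [spectrum1d()] on one common ppm axis.
#' @param noise_floor_k multiplier on the estimated baseline s.d.
#' @return list with `spectra` (normalized cohort) and `dilution_factors`
#'   (named per sample).
#' @export
pqn_normalize <- function(cohort, noise_floor_k = 5) {
  if (length(cohort) < 2L) stop("PQN needs at least 2 spectra")
  ax <- cohort[[1]]$ppm
  for (s in cohort)
    if (length(s$ppm) != length(ax) || max(abs(s$ppm - ax)) > 1e-9)
      stop("all spectra must share one common ppm axis")
  mat <- vapply(cohort, function(s) s$intensity, numeric(length(ax)))
  ref <- apply(mat, 1, stats::median)
  if (all(ref == 0)) stop("all-zero reference spectrum: cannot normalize")
  floor_ <- noise_floor_k * stats::mad(ref) + 1e-12 * max(abs(ref))
  eligible <- ref > floor_
  if (!any(eligible)) stop("degenerate reference: no variables above the noise floor")
  factors <- vapply(seq_along(cohort), function(i)
    stats::median(mat[eligible, i] / ref[eligible]), numeric(1))
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("non-positive or undefined quotient factor; check input spectra")
  names(factors) <- vapply(cohort, function(s) as.character(s$sample_id), character(1))
  out <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    spectrum1d(s$ppm, s$intensity / factors[i], s$sample_id, s$group, s$timepoint)
  })
  list(spectra = out, dilution_factors = factors)
}

trapz <- function(x, y) {
  o <- order(x); x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Quantify metabolites by fixed-window integration
#'
#' For each assignment, the trapezoidal integral of intensity over
#' `shift +/- halfwidth`. Windows of adjacent assignments are clipped at the
#' midpoint between their shifts so no two windows overlap (the serum panel
#' contains pairs only 0.03 ppm apart, where full +/-0.02 ppm windows would
#' integrate each other's peaks). A window overlapping the water cut is
#' reduced to its part outside the cut, with a warning; a window containing
#' no spectral points is an error. The result is linear in intensity
#' scaling, so ratios of integrals are concentration ratios.
#'
#' @param spec a preprocessed [spectrum1d()].
#' @param assignments a [metabolite_assignment()] table.
#' @param water_cut ppm interval excluded from any window.
#' @return named numeric vector of integrals (arbitrary units).
#' @export
quantify_metabolites <- function(spec, assignments, water_cut = c(4.67, 4.98)) {
  stopifnot(inherits(spec, "spectrum1d"))
  out <- numeric(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    x0 <- assignments$shift_ppm[i]
    others <- assignments$shift_ppm[-i]
    below <- others[others < x0]; above <- others[others > x0]
    hw <- assignments$window_halfwidth_ppm[i]
    lo <- x0 - min(hw, if (length(below)) (x0 - max(below)) / 2 else hw)
    hi <- x0 + min(hw, if (length(above)) (min(above) - x0) / 2 else hw)
    if (lo < water_cut[2] && hi > water_cut[1]) {
      warning(sprintf("window for %s overlaps the water cut; reduced",
                      assignments$name[i]))
      if (assignments$shift_ppm[i] < water_cut[1]) hi <- min(hi, water_cut[1])
      else lo <- max(lo, water_cut[2])
    }
    sel <- spec$ppm >= lo & spec$ppm <= hi
    if (sum(sel) < 2L)
      stop(sprintf("empty integration window for %s (%.3f ppm)",
                   assignments$name[i], assignments$shift_ppm[i]))
    out[i] <- trapz(spec$ppm[sel], spec$intensity[sel])
  }
  names(out) <- assignments$name
  out
}

#' Quantify a whole cohort
#'
#' @param spectra list of [spectrum1d()].
#' @param assignments a [metabolite_assignment()] table.
#' @return list with `quant` (sample-by-metabolite matrix) and `design`
#'   (data.frame `sample_id`, `group`, `timepoint`).
#' @export
quantify_cohort <- function(spectra, assignments) {
  quant <- t(vapply(spectra, quantify_metabolites, numeric(nrow(assignments)),
                    assignments = assignments))
  rownames(quant) <- vapply(spectra, function(s) as.character(s$sample_id), character(1))
  design <- data.frame(
    sample_id = rownames(quant),
    group = vapply(spectra, function(s) as.character(s$group), character(1)),
    timepoint = vapply(spectra, function(s) as.character(s$timepoint), character(1)),
    stringsAsFactors = FALSE)
  list(quant = quant, design = design)
}

#' Standard group comparisons for the four-group IR design
#' @return named list of `c(reference_arm, comparison_arm)` pairs; the fold
#'   change reported is `mean(comparison_arm) / mean(reference_arm)`.
#' @export
standard_comparisons <- function() {
  list("veh_IR_vs_sham" = c("vehicle_sham", "vehicle_IR"),
       "scn_IR_vs_sham" = c("SCN_sham", "SCN_IR"),
       "scn_IR_vs_veh_IR" = c("vehicle_IR", "SCN_IR"))
}

#' Per-metabolite fold changes with Welch tests
#'
#' For each metabolite and comparison: fold change as the ratio of group
#' means (comparison arm over reference arm) and a two-tailed Welch t-test
#' on the per-sample values. Per-metabolite tests are reported uncorrected
#' by default (matching common metabolomics tables); Benjamini-Hochberg is
#' available via `p_adjust = "BH"`.
#'
#' @param quant sample-by-metabolite matrix from [quantify_cohort()].
#' @param design data.frame with `sample_id` and `group`.
#' @param comparisons named list of `c(arm1, arm2)` group pairs; default
#'   [standard_comparisons()].
#' @param alpha significance threshold.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `fold_change_table`: `metabolite`,
#'   `comparison`, `fold_change`, `p_value`, `significant`.
#' @export
fold_change_table <- function(quant, design, comparisons = standard_comparisons(),
                              alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(names(comparisons)))
    names(comparisons) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  rows <- list()
  for (cn in names(comparisons)) {
    arms <- comparisons[[cn]]
    i1 <- design$group == arms[1]; i2 <- design$group == arms[2]
    if (sum(i1) < 2L || sum(i2) < 2L)
      stop("comparison ", cn, " needs >= 2 samples per arm")
    for (m in colnames(quant)) {
      x1 <- quant[i1, m]; x2 <- quant[i2, m]
      if (mean(x1) == 0) stop("zero mean in denominator arm for ", m)
      tt <- welch_t_test(x2, x1, comparison = cn)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, comparison = cn,
        fold_change = mean(x2) / mean(x1),
        p_value = tt$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH")
    out$p_value <- stats::ave(out$p_value, out$comparison,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  out$significant <- out$p_value < alpha
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Fold-change heatmap matrix
#'
#' Reshapes a [fold_change_table()] into a metabolite-by-comparison matrix
#' ordered by descending assignment shift (the conventional table order for
#' the serum panel), for display with a diverging palette centred at fold
#' 1.0 (hot above 1, cold below).
#'
#' @param entries a `fold_change_table`.
#' @param assignments optional [metabolite_assignment()] giving the shift
#'   order; defaults to the built-in serum panel when all names match,
#'   otherwise first-appearance order.
#' @return numeric matrix of class `fold_heatmap`.
#' @export
heatmap_matrix <- function(entries, assignments = NULL) {
  if (nrow(entries) == 0L) stop("empty fold-change table")
  mets <- unique(entries$metabolite)
  if (is.null(assignments) && all(mets %in% serum_panel$name))
    assignments <- serum_assignments()
  if (!is.null(assignments)) {
    ord <- assignments$name[order(-assignments$shift_ppm)]
    mets <- ord[ord %in% mets]
  }
  comps <- unique(entries$comparison)
  m <- matrix(NA_real_, length(mets), length(comps),
              dimnames = list(mets, comps))
  for (i in seq_len(nrow(entries)))
    m[entries$metabolite[i], entries$comparison[i]] <- entries$fold_change[i]
  class(m) <- c("fold_heatmap", "matrix", "array")
  m
}

#' @export
plot.fold_heatmap <- function(x, ..., max_log2 = NULL) {
  m <- unclass(x)
  lg <- log2(m)
  lim <- max_log2 %||% max(abs(lg[is.finite(lg)]), 0.1)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(lg[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2, cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Render a fold-change heatmap to a file
#' @param x `fold_heatmap` matrix.
#' @param path output file (`.png` or `.pdf`).
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(x, path, width = 5, height = 7) {
  if (grepl("\\.pdf$", path)) grDevices::pdf(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off())
  plot(x)
  invisible(path)
}
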