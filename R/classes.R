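#' Construct a 3-D volume image
#'
#' The MRI unit of work: a 3-D intensity array with per-axis voxel spacing in
#' millimetres and a contrast tag. T2* magnitude volumes are non-negative;
#' T1 inversion-recovery volumes come from a real-valued reconstruction and
#' may contain negative intensities.
#'
#' @param intensities 3-D numeric array, all values finite.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all strictly positive.
#' @param contrast `"T2STAR"` or `"T1IR"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(intensities, spacing, contrast = c("T2STAR", "T1IR")) {
  contrast <- match.arg(contrast)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-D array")
  if (length(intensities) == 0L) stop("`intensities` must be non-empty")
  if (!all(is.finite(intensities))) stop("`intensities` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(list(intensities = intensities, spacing = spacing, contrast = contrast),
            class = "volume_image")
}

#' Construct a 3-D mask
#'
#' @param voxels 3-D logical array.
#' @param spacing voxel spacing in mm, as for [volume_image()].
#' @param label one of `"LV"`, `"REPERFUSION"`, `"INFARCT"`, `"SALVAGE"`.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(voxels, spacing, label = c("LV", "REPERFUSION", "INFARCT", "SALVAGE")) {
  label <- match.arg(label)
  if (is.numeric(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3-D logical array")
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("`spacing` must be 3 positive values")
  structure(list(voxels = voxels, spacing = spacing, label = label), class = "mask3d")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_image %s> %d x %d x %d voxels, spacing %.4g/%.4g/%.4g mm\n",
              x$contrast, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask3d %s> %d x %d x %d voxels, %d set (%.1f%%)\n",
              x$label, d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' Construct a 1-D NMR spectrum
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity intensities, same length as `ppm`, finite.
#' @param sample_id sample identifier.
#' @param group group label, conventionally one of
#'   `"vehicle_sham"`, `"vehicle_IR"`, `"SCN_sham"`, `"SCN_IR"`.
#' @param timepoint e.g. `"24h"` or `"4w"`.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, sample_id = NA_character_,
                       group = NA_character_, timepoint = NA_character_) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) stop("ppm and intensity lengths differ")
  if (length(ppm) < 2L) stop("spectrum needs at least 2 points")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("`ppm` axis must be strictly monotone")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  structure(list(ppm = ppm, intensity = intensity, sample_id = sample_id,
                 group = group, timepoint = timepoint),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d %s [%s, %s]> %d points, %.3f..%.3f ppm\n",
              x$sample_id, x$group, x$timepoint, length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Metabolite assignment table
#'
#' Builds the named-shift table that drives fixed-window quantification.
#'
#' @param name metabolite labels.
#' @param shift_ppm chemical shifts (ppm), inside the spectral domain and
#'   outside the residual-water cut.
#' @param window_halfwidth_ppm positive integration half-widths (recycled).
#' @return data.frame of class `metabolite_assignment`.
#' @seealso [serum_assignments()] for the built-in 24-metabolite serum panel.
#' @export
metabolite_assignment <- function(name, shift_ppm, window_halfwidth_ppm = 0.02) {
  shift_ppm <- as.numeric(shift_ppm)
  hw <- rep_len(as.numeric(window_halfwidth_ppm), length(shift_ppm))
  if (length(name) != length(shift_ppm)) stop("name/shift length mismatch")
  if (any(!is.finite(shift_ppm))) stop("shifts must be finite")
  if (any(hw <= 0)) stop("window half-widths must be positive")
  if (any(shift_ppm < -1 | shift_ppm > 10))
    stop("assignment shifts must lie within -1.0..10.0 ppm")
  out <- data.frame(name = as.character(name), shift_ppm = shift_ppm,
                    window_halfwidth_ppm = hw, stringsAsFactors = FALSE)
  class(out) <- c("metabolite_assignment", "data.frame")
  out
}

#' Construct a 2-D histology section image
#'
#' @param pixels 2-D matrix (grayscale) or x-by-y-by-3 array (RGB).
#' @param um_per_pixel microns per pixel (> 0).
#' @param distance_um distance from the ligation site, on the fixed
#'   sectioning grid `seq(0, 4800, by = 600)` microns.
#' @param animal_id animal identifier.
#' @param channel `"DAPI"`, `"2D10G9"` or `"TRICHROME"`.
#' @return object of class `section_image`.
#' @export
section_image <- function(pixels, um_per_pixel, distance_um = 0,
                          animal_id = NA_character_,
                          channel = c("2D10G9", "TRICHROME", "DAPI")) {
  channel <- match.arg(channel)
  nd <- length(dim(pixels))
  if (!(nd == 2L || (nd == 3L && dim(pixels)[3] == 3L)))
    stop("`pixels` must be a 2-D matrix or an x-by-y-by-3 RGB array")
  if (um_per_pixel <= 0) stop("`um_per_pixel` must be positive")
  if (!distance_um %in% seq(0, 4800, by = 600))
    stop("`distance_um` must lie on the fixed grid 0, 600, ..., 4800")
  structure(list(pixels = pixels, um_per_pixel = um_per_pixel,
                 distance_um = distance_um, animal_id = animal_id,
                 channel = channel),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<section_image %s> %d x %d px @ %.3g um/px, %d um from ligation\n",
              x$channel, d[1], d[2], x$um_per_pixel, x$distance_um))
  invisible(x)
}

# internal: check two grids agree
check_same_geometry <- function(a_dim, a_sp, b_dim, b_sp, what = "inputs") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  if (max(abs(a_sp - b_sp)) > 1e-9)
    stop(sprintf("%s have mismatched voxel spacing", what))
  invisible(TRUE)
}
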