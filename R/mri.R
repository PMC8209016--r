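# Dual-contrast MRI volumetry: in-plane interpolation, relative-threshold
# segmentation of the iron-defined reperfusion territory (T2* signal void)
# and the gadolinium-defined infarct (squared T1-IR intensity), LV-mask
# clipping, and voxel-count volumetry with salvage computation.

# node-centred bilinear interpolation of one slice to (NX, NY)
interp_slice <- function(sl, NX, NY) {
  nx <- nrow(sl); ny <- ncol(sl)
  sx <- if (NX == 1L) 1 else 1 + (seq_len(NX) - 1) * (nx - 1) / (NX - 1)
  sy <- if (NY == 1L) 1 else 1 + (seq_len(NY) - 1) * (ny - 1) / (NY - 1)
  x0 <- pmin(floor(sx), nx - 1L); fx <- sx - x0
  y0 <- pmin(floor(sy), ny - 1L); fy <- sy - y0
  if (nx == 1L) { x0 <- rep(1L, NX); fx <- rep(0, NX) }
  if (ny == 1L) { y0 <- rep(1L, NY); fy <- rep(0, NY) }
  a <- sl[x0, y0, drop = FALSE]; b <- sl[x0 + (nx > 1L), y0, drop = FALSE]
  c_ <- sl[x0, y0 + (ny > 1L), drop = FALSE]; d <- sl[x0 + (nx > 1L), y0 + (ny > 1L), drop = FALSE]
  wx <- matrix(fx, NX, NY); wy <- matrix(fy, NX, NY, byrow = TRUE)
  a * (1 - wx) * (1 - wy) + b * wx * (1 - wy) + c_ * (1 - wx) * wy + d * wx * wy
}

#' Interpolate a volume in-plane to a finer grid
#'
#' Bilinear per-slice interpolation to the target in-plane matrix (default
#' 256 x 256), leaving the slice count untouched. In-plane spacing is
#' rescaled so the physical field of view is preserved. Downsampling is
#' refused.
#'
#' @param vol a [volume_image()].
#' @param target_inplane integer pair, target in-plane dimensions.
#' @return interpolated `volume_image`.
#' @export
interpolate_inplane <- function(vol, target_inplane = c(256L, 256L)) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$intensities)
  tgt <- as.integer(target_inplane)
  if (length(tgt) != 2L || any(tgt < d[1:2]))
    stop("in-plane interpolation must not downsample (target ", paste(tgt, collapse = "x"),
         " < source ", paste(d[1:2], collapse = "x"), ")")
  if (all(tgt == d[1:2])) return(vol)
  out <- array(0, c(tgt, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- interp_slice(vol$intensities[, , k], tgt[1], tgt[2])
  volume_image(out,
               spacing = c(vol$spacing[1] * d[1] / tgt[1],
                           vol$spacing[2] * d[2] / tgt[2],
                           vol$spacing[3]),
               contrast = vol$contrast)
}

#' Interpolate a mask in-plane (nearest-equivalent)
#'
#' Bilinear interpolation of the 0/1 mask followed by a 0.5 cut (ties in).
#' Used to carry masks onto the interpolated grid.
#'
#' @param mask a [mask3d()].
#' @param target_inplane integer pair.
#' @return `mask3d` on the target grid.
#' @export
interpolate_mask_inplane <- function(mask, target_inplane = c(256L, 256L)) {
  stopifnot(inherits(mask, "mask3d"))
  v <- volume_image(array(as.numeric(mask$voxels), dim(mask$voxels)),
                    mask$spacing, "T2STAR")
  vi <- interpolate_inplane(v, target_inplane)
  mask3d(vi$intensities >= 0.5, vi$spacing, mask$label)
}

#' Volume of a mask in cubic millimetres
#'
#' @param mask a [mask3d()].
#' @return `|true voxels| * dx * dy * dz` (mm^3).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "mask3d"))
  sum(mask$voxels) * prod(mask$spacing)
}

#' Segment the reperfusion territory on a T2* volume
#'
#' The iron-labelled reperfused territory appears as a signal void, so the
#' segmentation keeps LV voxels whose intensity is at or below
#' `fraction * max(intensity over the LV mask)` ("threshold from a minimum
#' to 0.66 of maximum"). The maximum is taken over the LV mask, not the full
#' field of view. Ties at the threshold are included.
#'
#' @param vol T2* [volume_image()].
#' @param lv LV [mask3d()], same geometry, non-empty.
#' @param fraction relative threshold, default 0.66.
#' @param direction `"le"` (default: keep the low-signal band, iron void) or
#'   `"ge"` (inverted polarity).
#' @return `mask3d` labelled `REPERFUSION`, a subset of `lv`.
#' @export
segment_reperfusion_t2star <- function(vol, lv, fraction = 0.66,
                                       direction = c("le", "ge")) {
  direction <- match.arg(direction)
  stopifnot(inherits(vol, "volume_image"), inherits(lv, "mask3d"))
  check_same_geometry(dim(vol$intensities), vol$spacing, dim(lv$voxels), lv$spacing,
                      "T2* volume and LV mask")
  if (!any(lv$voxels)) stop("LV mask is empty")
  thr <- fraction * max(vol$intensities[lv$voxels])
  sel <- if (direction == "le") vol$intensities <= thr else vol$intensities >= thr
  mask3d(sel & lv$voxels, vol$spacing, "REPERFUSION")
}

#' Segment the infarct on a T1 inversion-recovery volume
#'
#' Voxel intensities of the signed real reconstruction are squared (so
#' gadolinium enhancement of either polarity is captured), then LV voxels
#' with squared intensity at or above `fraction * max(squared intensity over
#' the LV mask)` are kept and clipped to the reperfusion mask, so salvage
#' can never be negative. Ties at the threshold are included.
#'
#' @param vol T1-IR [volume_image()].
#' @param lv LV [mask3d()].
#' @param reperfusion reperfusion [mask3d()], a subset of `lv`.
#' @param fraction relative threshold, default 0.10.
#' @param square if `FALSE`, threshold raw (absolute) intensities instead of
#'   squared ones.
#' @param max_of if `"squared"` (default) the maximum defining the threshold
#'   is of squared intensities; `"raw"` squares the threshold of the raw
#'   maximum instead.
#' @param clip_to_reperfusion intersect with the reperfusion mask (default
#'   `TRUE`).
#' @return `mask3d` labelled `INFARCT`.
#' @export
segment_infarct_t1 <- function(vol, lv, reperfusion, fraction = 0.10,
                               square = TRUE, max_of = c("squared", "raw"),
                               clip_to_reperfusion = TRUE) {
  max_of <- match.arg(max_of)
  stopifnot(inherits(vol, "volume_image"), inherits(lv, "mask3d"),
            inherits(reperfusion, "mask3d"))
  check_same_geometry(dim(vol$intensities), vol$spacing, dim(lv$voxels), lv$spacing,
                      "T1 volume and LV mask")
  check_same_geometry(dim(lv$voxels), lv$spacing, dim(reperfusion$voxels),
                      reperfusion$spacing, "LV and reperfusion masks")
  if (any(reperfusion$voxels & !lv$voxels))
    stop("reperfusion mask must be contained in the LV mask")
  sq <- if (square) vol$intensities^2 else abs(vol$intensities)
  mx <- if (max_of == "squared" || !square) max(sq[lv$voxels])
        else max(abs(vol$intensities)[lv$voxels])^2
  if (mx == 0) stop("all-zero volume over the LV mask: threshold undefined")
  sel <- sq >= fraction * mx & lv$voxels
  if (clip_to_reperfusion) sel <- sel & reperfusion$voxels
  mask3d(sel, vol$spacing, "INFARCT")
}

#' Volumetry of the LV / reperfusion / infarct mask chain
#'
#' Computes the four volumes (salvage = reperfusion - infarct, exactly, from
#' voxel counts) and the five normalized percentages. The containment chain
#' `infarct` in `reperfusion` in `lv` is enforced. When the reperfusion
#' volume is zero, reperfusion-normalized percentages are `NA` (flagged
#' undefined), never silently 0.
#'
#' @param lv,reperfusion,infarct [mask3d()] objects on one grid.
#' @return object of class `volumetry_result`: a one-row data.frame with
#'   columns `lv_volume`, `reperfusion_volume`, `infarct_volume`,
#'   `salvage_volume` (mm^3), `infarct_pct_of_reperfusion`,
#'   `salvage_pct_of_reperfusion`, `reperfusion_pct_of_lv`,
#'   `infarct_pct_of_lv`, `salvage_pct_of_lv`. Integer voxel counts are
#'   carried in the `voxel_counts` attribute so conservation can be checked
#'   exactly.
#' @export
compute_volumetry <- function(lv, reperfusion, infarct) {
  stopifnot(inherits(lv, "mask3d"), inherits(reperfusion, "mask3d"),
            inherits(infarct, "mask3d"))
  check_same_geometry(dim(lv$voxels), lv$spacing, dim(reperfusion$voxels),
                      reperfusion$spacing, "masks")
  check_same_geometry(dim(lv$voxels), lv$spacing, dim(infarct$voxels),
                      infarct$spacing, "masks")
  if (any(reperfusion$voxels & !lv$voxels) || any(infarct$voxels & !reperfusion$voxels))
    stop("containment violated: need infarct ⊆ reperfusion ⊆ LV")
  vv <- prod(lv$spacing)
  n_lv <- sum(lv$voxels); n_rep <- sum(reperfusion$voxels); n_inf <- sum(infarct$voxels)
  n_sal <- n_rep - n_inf
  pct <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  out <- data.frame(
    lv_volume = n_lv * vv,
    reperfusion_volume = n_rep * vv,
    infarct_volume = n_inf * vv,
    salvage_volume = n_sal * vv,
    infarct_pct_of_reperfusion = pct(n_inf, n_rep),
    salvage_pct_of_reperfusion = pct(n_sal, n_rep),
    reperfusion_pct_of_lv = pct(n_rep, n_lv),
    infarct_pct_of_lv = pct(n_inf, n_lv),
    salvage_pct_of_lv = pct(n_sal, n_lv)
  )
  attr(out, "voxel_counts") <- c(lv = n_lv, reperfusion = n_rep,
                                 infarct = n_inf, salvage = n_sal)
  class(out) <- c("volumetry_result", "data.frame")
  out
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat("<volumetry_result> (mm^3)\n")
  cat(sprintf("  LV %.3f | reperfusion %.3f | infarct %.3f | salvage %.3f\n",
              x$lv_volume, x$reperfusion_volume, x$infarct_volume, x$salvage_volume))
  cat(sprintf("  infarct %.1f%% / salvage %.1f%% of reperfusion; reperfusion %.1f%% of LV\n",
              x$infarct_pct_of_reperfusion, x$salvage_pct_of_reperfusion,
              x$reperfusion_pct_of_lv))
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [mask3d()] objects or logical arrays of one shape.
#' @return `2|A and B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "mask3d")) a <- a$voxels
  if (inherits(b, "mask3d")) b <- b$voxels
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Run the full MRI volumetry pipeline
#'
#' Deterministic composition: in-plane interpolation of both contrasts and
#' the LV mask to a common finer grid, T2* reperfusion segmentation, T1-IR
#' infarct segmentation, and volumetry. Optionally writes the three masks as
#' uint8 NIfTI files and appends the result row to `results.csv`.
#'
#' @param t2star,t1ir [volume_image()] objects on one grid (phantoms and
#'   resampled acquisitions are co-registered by construction).
#' @param lv LV [mask3d()].
#' @param config list of overrides: `target_inplane` (default `c(256, 256)`),
#'   `t2_fraction` (0.66), `t1_fraction` (0.10), `t2_direction`,
#'   `t1_square`, `t1_max_of`, `clip_to_reperfusion`.
#' @param out_dir optional output directory for masks + CSV.
#' @param id row label used in the results CSV.
#' @return list with `result` ([compute_volumetry()] row), `masks`
#'   (`lv`, `reperfusion`, `infarct` on the interpolated grid).
#' @export
run_mri_pipeline <- function(t2star, t1ir, lv, config = list(),
                             out_dir = NULL, id = "sample") {
  cfg <- utils::modifyList(list(target_inplane = c(256L, 256L),
                                t2_fraction = 0.66, t1_fraction = 0.10,
                                t2_direction = "le", t1_square = TRUE,
                                t1_max_of = "squared",
                                clip_to_reperfusion = TRUE), config)
  t2i <- interpolate_inplane(t2star, cfg$target_inplane)
  t1i <- interpolate_inplane(t1ir, cfg$target_inplane)
  lvi <- interpolate_mask_inplane(lv, cfg$target_inplane)
  rep_mask <- segment_reperfusion_t2star(t2i, lvi, cfg$t2_fraction, cfg$t2_direction)
  inf_mask <- segment_infarct_t1(t1i, lvi, rep_mask, cfg$t1_fraction,
                                 cfg$t1_square, cfg$t1_max_of,
                                 cfg$clip_to_reperfusion)
  res <- compute_volumetry(lvi, rep_mask, inf_mask)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nifti(lvi, file.path(out_dir, paste0(id, "_lv.nii.gz")))
    write_nifti(rep_mask, file.path(out_dir, paste0(id, "_reperfusion.nii.gz")))
    write_nifti(inf_mask, file.path(out_dir, paste0(id, "_infarct.nii.gz")))
    csv <- file.path(out_dir, "results.csv")
    row <- cbind(data.frame(id = id), as.data.frame(res))
    utils::write.table(row, csv, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv), append = file.exists(csv))
  }
  list(result = res, masks = list(lv = lvi, reperfusion = rep_mask, infarct = inf_mask))
}
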