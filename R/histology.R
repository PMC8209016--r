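# Section-level quantification: fluorescence thresholding at the fixed
# 150/350 grayscale levels, colour-rule collagen segmentation of trichrome
# images, distance-to-ligation profiles and the collagen-oxidation
# correlation.

#' Threshold quantification of a 2D10G9 fluorescence section
#'
#' Tissue is defined as pixels strictly above the background threshold;
#' positivity as pixels strictly above the positive threshold ("over 150" /
#' "over 350" grayscale). Mean intensity is computed over tissue pixels
#' only. Raw stored grayscale values are used; no normalization is applied
#' before thresholding, so the same thresholds are comparable across a
#' dataset.
#'
#' @param img grayscale [section_image()] or numeric matrix.
#' @param background_threshold,positive_threshold grayscale thresholds with
#'   `background < positive` (defaults 150 and 350).
#' @return list with `mean_intensity`, `percent_positive`, `n_tissue`.
#' @export
quantify_fluorescence <- function(img, background_threshold = 150,
                                  positive_threshold = 350) {
  px <- if (inherits(img, "section_image")) img$pixels else img
  if (length(dim(px)) != 2L) stop("fluorescence quantification needs a grayscale image")
  if (background_threshold >= positive_threshold)
    stop("background threshold must be below positive threshold")
  tissue <- px > background_threshold
  n_t <- sum(tissue)
  if (n_t == 0L) stop("no tissue: no pixel above the background threshold")
  list(mean_intensity = mean(px[tissue]),
       percent_positive = 100 * sum(px > positive_threshold) / n_t,
       n_tissue = n_t)
}

#' Colour-rule segmentation of a trichrome section
#'
#' Partitions every pixel into background / myocardium / collagen with an
#' explicit hue-saturation rule: low-saturation pixels are background;
#' among saturated (tissue) pixels, hues in the blue-purple band are
#' collagen and the rest (red-dominant) myocardium. This replaces opaque
#' trained pixel classifiers with a documented, tunable rule; the defaults
#' suit typical trichrome stains (collagen blue/purple, myocardium red).
#'
#' @param img RGB [section_image()] or x-by-y-by-3 array (0-255 or 0-1).
#' @param saturation_min minimum HSV saturation for a tissue pixel.
#' @param collagen_hue hue band (degrees, 0-360) classified as collagen.
#' @return list of logical masks: `collagen`, `myocardium`, `tissue`,
#'   `background` (a partition: collagen + myocardium + background = all).
#' @export
segment_collagen <- function(img, saturation_min = 0.15,
                             collagen_hue = c(150, 300)) {
  px <- if (inherits(img, "section_image")) img$pixels else img
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("collagen segmentation needs an RGB image")
  if (max(px) > 1) px <- px / 255
  d <- dim(px)[1:2]
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  sat <- matrix(hsv[2, ], d[1], d[2])
  hue <- matrix(hsv[1, ] * 360, d[1], d[2])
  tissue <- sat >= saturation_min
  collagen <- tissue & hue >= collagen_hue[1] & hue <= collagen_hue[2]
  list(collagen = collagen,
       myocardium = tissue & !collagen,
       tissue = tissue,
       background = !tissue)
}

#' Collagen area from segmentation masks
#'
#' @param masks mask list from [segment_collagen()] (or a logical collagen
#'   mask, in which case `tissue` must be given).
#' @param um_per_pixel microns per pixel.
#' @param tissue optional tissue mask when `masks` is a bare collagen mask.
#' @return list with `area_um2` (`|collagen| * um_per_pixel^2`) and
#'   `percent_of_tissue`.
#' @export
collagen_area <- function(masks, um_per_pixel, tissue = NULL) {
  if (is.list(masks)) { collagen <- masks$collagen; tissue <- masks$tissue }
  else collagen <- masks
  if (is.null(tissue) || sum(tissue) == 0L) stop("empty tissue mask")
  list(area_um2 = sum(collagen) * um_per_pixel^2,
       percent_of_tissue = 100 * sum(collagen) / sum(tissue))
}

#' Quantify one section pair into a SectionQuant row
#'
#' @param fluorescence grayscale [section_image()] (2D10G9 channel).
#' @param trichrome RGB [section_image()].
#' @param background_threshold,positive_threshold fluorescence thresholds.
#' @return one-row data.frame: `animal_id`, `distance_um`, `mean_intensity`,
#'   `percent_positive`, `collagen_area_um2`, `collagen_percent`.
#' @export
quantify_section <- function(fluorescence, trichrome,
                             background_threshold = 150,
                             positive_threshold = 350) {
  fl <- quantify_fluorescence(fluorescence, background_threshold, positive_threshold)
  seg <- segment_collagen(trichrome)
  ca <- collagen_area(seg, trichrome$um_per_pixel)
  data.frame(animal_id = fluorescence$animal_id,
             distance_um = fluorescence$distance_um,
             mean_intensity = fl$mean_intensity,
             percent_positive = fl$percent_positive,
             collagen_area_um2 = ca$area_um2,
             collagen_percent = ca$percent_of_tissue,
             stringsAsFactors = FALSE)
}

#' Distance-to-ligation profile of a section metric
#'
#' Group mean and SEM of `metric` at each sectioning distance. Distances of
#' the fixed grid absent from the data are flagged in the `missing`
#' attribute, never imputed.
#'
#' @param quants data.frame of per-section quantifications with at least
#'   `distance_um` and the metric column; a `group` column is used when
#'   present (otherwise one pooled group).
#' @param metric column name, e.g. `"percent_positive"`.
#' @return data.frame `group`, `distance_um`, `n`, `mean`, `sem`, with
#'   attribute `missing` listing absent grid distances per group.
#' @export
distance_profile <- function(quants, metric) {
  if (nrow(quants) == 0L) stop("empty input")
  if (!metric %in% names(quants)) stop("unknown metric column: ", metric)
  grp <- if ("group" %in% names(quants)) quants$group else rep("all", nrow(quants))
  v <- quants[[metric]]
  agg <- stats::aggregate(v, list(group = grp, distance_um = quants$distance_um),
                          function(z) c(n = length(z), mean = mean(z), sem = sem(z)))
  out <- data.frame(group = agg$group, distance_um = agg$distance_um,
                    n = agg$x[, "n"], mean = agg$x[, "mean"], sem = agg$x[, "sem"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$distance_um), ]
  rownames(out) <- NULL
  grid <- seq(0, 4800, by = 600)
  miss <- lapply(split(out$distance_um, out$group), function(d) setdiff(grid, d))
  attr(out, "missing") <- miss
  out
}

#' Correlation between collagen content and oxidative damage
#'
#' Pearson correlation between `collagen_percent` and `percent_positive`
#' across sections, pooled (optionally per group) or per animal.
#'
#' @param quants per-section data.frame with `collagen_percent`,
#'   `percent_positive` and, as needed, `group` / `animal_id` columns.
#' @param scope `"pooled"` (one r per group, plus an `all` row) or
#'   `"per_animal"`.
#' @return data.frame `scope`, `n`, `r`, `p`.
#' @export
correlate_collagen_oxidation <- function(quants, scope = c("pooled", "per_animal")) {
  scope <- match.arg(scope)
  one <- function(d, label) {
    pr <- pearson_r(d$collagen_percent, d$percent_positive)
    data.frame(scope = label, n = pr$n, r = pr$r, p = pr$p, stringsAsFactors = FALSE)
  }
  if (scope == "pooled") {
    out <- one(quants, "all")
    if ("group" %in% names(quants) && length(unique(quants$group)) > 1L)
      out <- rbind(out, do.call(rbind, lapply(split(quants, quants$group), function(d)
        one(d, unique(d$group)))))
  } else {
    if (!"animal_id" %in% names(quants)) stop("per-animal scope needs `animal_id`")
    out <- do.call(rbind, lapply(split(quants, quants$animal_id), function(d)
      one(d, unique(d$animal_id))))
  }
  rownames(out) <- NULL
  out
}
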