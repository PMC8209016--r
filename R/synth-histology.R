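#' Construct a histology section ground truth
#'
#' @param distance_um distance from the ligation site, on the fixed grid
#'   `seq(0, 4800, by = 600)` microns.
#' @param true_positive_fraction fraction of tissue pixels carrying positive
#'   (oxidation-marker) fluorescence, in \[0, 1\].
#' @param true_collagen_fraction fraction of tissue pixels that are collagen
#'   in the trichrome image, in \[0, 1\].
#' @param um_per_pixel microns per pixel.
#' @param animal_id optional animal label carried through to images.
#' @return object of class `section_truth`.
#' @export
section_truth <- function(distance_um, true_positive_fraction,
                          true_collagen_fraction, um_per_pixel = 6.45,
                          animal_id = NA_character_) {
  if (!distance_um %in% seq(0, 4800, by = 600))
    stop("`distance_um` must lie on the fixed grid 0, 600, ..., 4800")
  if (true_positive_fraction < 0 || true_positive_fraction > 1 ||
      true_collagen_fraction < 0 || true_collagen_fraction > 1)
    stop("truth fractions must lie in [0, 1]")
  if (um_per_pixel <= 0) stop("`um_per_pixel` must be positive")
  structure(list(distance_um = distance_um,
                 true_positive_fraction = true_positive_fraction,
                 true_collagen_fraction = true_collagen_fraction,
                 um_per_pixel = um_per_pixel,
                 animal_id = animal_id),
            class = "section_truth")
}

#' Generate a synthetic histology section pair
#'
#' Emits a 2D10G9-style grayscale fluorescence image and a trichrome-style
#' RGB image sharing one circular tissue region. In the fluorescence image
#' background pixels sit below the 150-grayscale background threshold,
#' tissue pixels sit between 150 and 350, and an exact
#' `round(f * n_tissue)`-pixel subset (seeded random positions) exceeds the
#' 350 positivity threshold. In the RGB image an exact collagen-fraction
#' subset of tissue pixels is blue-class, the remainder red-class
#' (myocardium), and the background is a pale low-saturation grey.
#' Images are noise-free by default so threshold round-trips are exact.
#'
#' @param truth a [section_truth()].
#' @param image_shape integer pair, image dimensions in pixels.
#' @param seed integer seed.
#' @param noise_sd optional Gaussian jitter s.d. added to fluorescence
#'   grayscale values (kept small; clipped so no pixel crosses a threshold
#'   class boundary).
#' @return list with `fluorescence` and `trichrome` ([section_image()]) and
#'   the input `truth`.
#' @export
generate_histology_section <- function(truth, image_shape = c(192L, 192L),
                                       seed = 1L, noise_sd = 0) {
  stopifnot(inherits(truth, "section_truth"))
  nx <- as.integer(image_shape[1]); ny <- as.integer(image_shape[2])
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`))
  tissue <- r <= 0.42 * min(nx, ny)
  n_t <- sum(tissue)

  with_seed(seed, {
    # fluorescence: background < 150 < tissue <= 350 < positive
    img <- matrix(stats::runif(nx * ny, 60, 140), nx, ny)
    img[tissue] <- stats::runif(n_t, 170, 340)
    k_pos <- round(truth$true_positive_fraction * n_t)
    t_idx <- which(tissue)
    pos_idx <- if (k_pos > 0) sample(t_idx, k_pos) else integer(0)
    img[pos_idx] <- stats::runif(k_pos, 400, 900)
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      img[!tissue] <- pmin(img[!tissue], 149)
      img[t_idx] <- pmin(pmax(img[t_idx], 151), 349)
      img[pos_idx] <- pmax(img[pos_idx], 351)
    }
    img <- round(img)

    # trichrome RGB, 8-bit
    rgb <- array(0, dim = c(nx, ny, 3))
    n_bg <- nx * ny - n_t
    bg_base <- stats::runif(n_bg, 230, 250)
    for (ch in 1:3) rgb[, , ch][!tissue] <- bg_base + stats::runif(n_bg, -4, 4)
    # myocardium: red-dominant
    rgb[, , 1][tissue] <- stats::runif(n_t, 170, 220)
    rgb[, , 2][tissue] <- stats::runif(n_t, 40, 80)
    rgb[, , 3][tissue] <- stats::runif(n_t, 60, 100)
    k_col <- round(truth$true_collagen_fraction * n_t)
    col_idx <- if (k_col > 0) sample(t_idx, k_col) else integer(0)
    rgb[, , 1][col_idx] <- stats::runif(k_col, 40, 90)
    rgb[, , 2][col_idx] <- stats::runif(k_col, 60, 110)
    rgb[, , 3][col_idx] <- stats::runif(k_col, 160, 220)
    rgb <- round(rgb)

    list(
      fluorescence = section_image(img, truth$um_per_pixel, truth$distance_um,
                                   truth$animal_id, "2D10G9"),
      trichrome = section_image(rgb, truth$um_per_pixel, truth$distance_um,
                                truth$animal_id, "TRICHROME"),
      truth = truth
    )
  })
}

#' Generate a cohort of section truths with planted distance decay and
#' collagen-oxidation correlation
#'
#' Produces one [section_truth()] row per animal and sectioning distance.
#' The positive-fluorescence fraction decays linearly with distance to the
#' ligation plus Gaussian animal/section noise; the collagen fraction is
#' constructed to correlate with the positive fraction at a planted Pearson
#' coefficient (population value, before clamping to \[0.02, 0.98\]).
#'
#' @param n_animals animals per group.
#' @param distances_um sectioning distances; default the full fixed grid.
#' @param pos_at_ligation mean positive fraction at 0 um.
#' @param pos_slope_per_mm decrease in positive fraction per mm of distance.
#' @param pos_noise_sd per-section noise s.d. on the positive fraction.
#' @param collagen_mean,collagen_sd collagen fraction mean and s.d.
#' @param target_r planted Pearson correlation between collagen and positive
#'   fractions (e.g. -0.5).
#' @param um_per_pixel metadata carried onto each truth.
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `distance_um`,
#'   `true_positive_fraction`, `true_collagen_fraction`, `um_per_pixel`.
#' @export
generate_section_cohort <- function(n_animals = 6L,
                                    distances_um = seq(0, 4800, by = 600),
                                    pos_at_ligation = 0.55,
                                    pos_slope_per_mm = 0.06,
                                    pos_noise_sd = 0.08,
                                    collagen_mean = 0.25,
                                    collagen_sd = 0.08,
                                    target_r = -0.5,
                                    um_per_pixel = 6.45,
                                    seed = 1L) {
  stopifnot(all(distances_um %in% seq(0, 4800, by = 600)), abs(target_r) <= 1)
  trend <- pos_at_ligation - pos_slope_per_mm * distances_um / 1000
  n <- n_animals * length(distances_um)
  trend_all <- rep(trend, times = n_animals)
  sd_trend <- stats::sd(trend_all) * sqrt((n - 1) / n)
  sd_pos <- sqrt(sd_trend^2 + pos_noise_sd^2)
  with_seed(seed, {
    e <- stats::rnorm(n, 0, pos_noise_sd)
    pos <- trend_all + e
    zpos <- (pos - mean(trend_all)) / sd_pos
    col <- collagen_mean + collagen_sd * (target_r * zpos +
             sqrt(1 - target_r^2) * stats::rnorm(n))
    data.frame(
      animal_id = rep(sprintf("A%02d", seq_len(n_animals)),
                      each = length(distances_um)),
      distance_um = rep(distances_um, times = n_animals),
      true_positive_fraction = pmin(pmax(pos, 0.02), 0.98),
      true_collagen_fraction = pmin(pmax(col, 0.02), 0.98),
      um_per_pixel = um_per_pixel,
      stringsAsFactors = FALSE
    )
  })
}
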