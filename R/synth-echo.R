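#' Default echo design means
#'
#' A convenience builder for the per-group, per-site, per-timepoint mean
#' M-mode diameters consumed by [generate_echo_series()]: all groups share a
#' common baseline (LVd 8.0 mm, LVs 4.5 mm) and the `vehicle_IR` group
#' dilates in systole from 1 week after surgery, emulating adverse
#' remodelling after an untreated infarct.
#'
#' @param lves_gap_mm planted end-systolic dilatation of the `vehicle_IR`
#'   group at 1, 2 and 4 weeks (mm).
#' @param lvd_mm,lvs_mm shared baseline diastolic/systolic diameters (mm).
#' @return data.frame with columns `group`, `site`, `timepoint`, `lvd_mm`,
#'   `lvs_mm`.
#' @export
default_echo_effects <- function(lves_gap_mm = 1.5, lvd_mm = 8, lvs_mm = 4.5) {
  groups <- c("vehicle_sham", "vehicle_IR", "SCN_sham", "SCN_IR")
  sites <- c("base", "mid", "apex")
  tps <- c("pre", "48h", "1w", "2w", "4w")
  g <- expand.grid(group = groups, site = sites, timepoint = tps,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$lvd_mm <- lvd_mm
  g$lvs_mm <- lvs_mm
  late <- g$group == "vehicle_IR" & g$timepoint %in% c("1w", "2w", "4w")
  g$lvs_mm[late] <- g$lvs_mm[late] + lves_gap_mm
  g
}

#' Simulate an echocardiography M-mode series
#'
#' Draws seeded normal deviates around the supplied group means for every
#' animal, site and timepoint.
#'
#' @param group_effects data.frame of design means as returned by
#'   [default_echo_effects()] (columns `group`, `site`, `timepoint`,
#'   `lvd_mm`, `lvs_mm`).
#' @param sd measurement/animal noise s.d. (mm), applied independently to
#'   both diameters.
#' @param n_per_group animals per group.
#' @param seed integer seed.
#' @return list with `records` (data.frame: `animal_id`, `group`, `site`,
#'   `timepoint`, `lvd_mm`, `lvs_mm`) and `truth` (the design means, `sd`,
#'   `n_per_group`, `seed`).
#' @export
generate_echo_series <- function(group_effects = default_echo_effects(),
                                 sd = 0.5, n_per_group = 8L, seed = 1L) {
  need <- c("group", "site", "timepoint", "lvd_mm", "lvs_mm")
  if (!all(need %in% names(group_effects)))
    stop("`group_effects` must have columns ", paste(need, collapse = ", "))
  if (any(group_effects$lvs_mm <= 0) ||
      any(group_effects$lvd_mm <= group_effects$lvs_mm))
    stop("design means must satisfy lvd > lvs > 0")
  if (sd < 0) stop("`sd` must be >= 0")
  groups <- unique(group_effects$group)
  rec <- do.call(rbind, lapply(seq_len(n_per_group), function(a) {
    r <- group_effects
    r$animal_id <- paste0(r$group, "_", sprintf("%02d", a))
    r
  }))
  rec <- rec[order(rec$group, rec$animal_id, rec$site, rec$timepoint), ]
  rownames(rec) <- NULL
  rec <- with_seed(seed, {
    if (sd > 0) {
      rec$lvd_mm <- rec$lvd_mm + stats::rnorm(nrow(rec), 0, sd)
      rec$lvs_mm <- rec$lvs_mm + stats::rnorm(nrow(rec), 0, sd)
    }
    rec
  })
  list(records = rec[, c("animal_id", "group", "site", "timepoint", "lvd_mm", "lvs_mm")],
       truth = list(group_effects = group_effects, sd = sd,
                    n_per_group = n_per_group, seed = seed))
}

#' Simulate ion-chromatography standard-curve data for thiocyanate
#'
#' Calibration points at fixed concentrations spanning 0-200 uM with
#' multiplicative noise of the stated coefficient of variation, plus peak
#' areas for a set of unknowns at the same slope.
#'
#' @param true_unknowns true unknown concentrations (uM), all >= 0.
#' @param slope detector response (area per uM).
#' @param intercept curve intercept (area units).
#' @param noise_cv multiplicative noise CV (fraction).
#' @param calibration_um calibration concentrations; default
#'   `seq(0, 200, by = 25)`.
#' @param seed integer seed.
#' @return list with `calibration` (data.frame `concentration_um`,
#'   `peak_area`), `unknowns` (data.frame `sample_id`, `peak_area`) and
#'   `truth` (`slope`, `intercept`, `true_unknowns`, `seed`).
#' @export
generate_standard_curve_data <- function(true_unknowns = 110,
                                         slope = 0.5, intercept = 0,
                                         noise_cv = 0.02,
                                         calibration_um = seq(0, 200, by = 25),
                                         seed = 1L) {
  if (any(true_unknowns < 0)) stop("unknown concentrations must be >= 0")
  if (slope <= 0) stop("`slope` must be positive")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  with_seed(seed, {
    mult <- function(n) if (noise_cv > 0) 1 + stats::rnorm(n, 0, noise_cv) else rep(1, length.out = n)
    cal_area <- (intercept + slope * calibration_um) * mult(length(calibration_um))
    unk_area <- (intercept + slope * true_unknowns) * mult(length(true_unknowns))
    list(calibration = data.frame(concentration_um = calibration_um,
                                  peak_area = cal_area),
         unknowns = data.frame(sample_id = sprintf("U%02d", seq_along(true_unknowns)),
                               peak_area = unk_area),
         truth = list(slope = slope, intercept = intercept,
                      true_unknowns = true_unknowns, seed = seed))
  })
}
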