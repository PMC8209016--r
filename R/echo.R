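# Echocardiographic indices and thiocyanate quantification from the
# ion-chromatography standard curve.

#' Fractional shortening
#'
#' `100 * (LVd - LVs) / LVd`, the M-mode contractility index. Vectorized.
#'
#' @param lv_diastole end-diastolic diameter (mm), > 0.
#' @param lv_systole end-systolic diameter (mm).
#' @return fractional shortening in percent.
#' @export
fractional_shortening <- function(lv_diastole, lv_systole) {
  if (any(lv_diastole <= 0)) stop("LV diastolic diameter must be positive")
  100 * (lv_diastole - lv_systole) / lv_diastole
}

#' Echo trajectory summary with group-comparison statistics
#'
#' Summarizes an M-mode record table into per-group, per-site,
#' per-timepoint means with SEM, and runs a two-way ANOVA
#' (group x timepoint) per site with the configured post-hoc. Records
#' violating `lvd >= lvs > 0` are flagged in the `flagged` attribute, not
#' dropped. Cells with fewer than 2 records are rejected and listed.
#'
#' @param records data.frame with columns `animal_id`, `group`, `site`,
#'   `timepoint`, `lvd_mm`, `lvs_mm` and optionally `lved_area`,
#'   `lves_area`.
#' @param metric `"FS"` (fractional shortening from the diameters),
#'   `"LVED"` or `"LVES"` (areas when present, else diameters).
#' @param posthoc `"dunnett"` (default), `"sidak"` or `"none"`.
#' @param control_group Dunnett control level (default `"vehicle_IR"`, the
#'   untreated infarct group every other arm is compared against).
#' @param alpha significance level.
#' @return list with `summary` (group/site/timepoint mean, sem, n),
#'   `stats` (per-site [two_way_anova_posthoc()] results) and `metric`.
#' @export
echo_trajectory <- function(records, metric = c("FS", "LVED", "LVES"),
                            posthoc = c("dunnett", "sidak", "none"),
                            control_group = "vehicle_IR", alpha = 0.05) {
  metric <- match.arg(metric)
  posthoc <- match.arg(posthoc)
  val <- switch(metric,
    FS = fractional_shortening(records$lvd_mm, records$lvs_mm),
    LVED = records$lved_area %||% records$lvd_mm,
    LVES = records$lves_area %||% records$lvs_mm)
  flagged <- which(!(records$lvd_mm >= records$lvs_mm & records$lvs_mm > 0))
  d <- data.frame(group = records$group, site = records$site,
                  timepoint = records$timepoint, value = val,
                  stringsAsFactors = FALSE)
  tab <- table(d$group, d$site, d$timepoint)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)
    stop("cells with < 2 records: ",
         paste(apply(bad, 1, function(i)
           sprintf("(%s, %s, %s)", dimnames(tab)[[1]][i[1]],
                   dimnames(tab)[[2]][i[2]], dimnames(tab)[[3]][i[3]])),
           collapse = ", "))
  }
  agg <- stats::aggregate(value ~ group + site + timepoint, d,
                          function(z) c(n = length(z), mean = mean(z), sem = sem(z)))
  summ <- data.frame(agg[c("group", "site", "timepoint")],
                     n = agg$value[, "n"], mean = agg$value[, "mean"],
                     sem = agg$value[, "sem"], stringsAsFactors = FALSE)
  summ <- summ[order(summ$site, summ$group, summ$timepoint), ]
  rownames(summ) <- NULL
  stats_by_site <- lapply(split(d, d$site), function(ds)
    two_way_anova_posthoc(ds, "value", "group", "timepoint",
                          posthoc = posthoc,
                          control_level = if (posthoc == "dunnett") control_group else NULL,
                          alpha = alpha))
  structure(list(summary = summ, stats = stats_by_site, metric = metric),
            flagged = flagged)
}

#' Fit the thiocyanate standard curve
#'
#' Ordinary least-squares line through the calibration points, with a
#' warning when r-squared falls below 0.99 (a chromatography curve should
#' be essentially linear).
#'
#' @param concentrations calibration concentrations (uM), >= 3 distinct
#'   points.
#' @param peak_areas detector peak areas.
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, plus the calibration data.
#' @export
fit_standard_curve <- function(concentrations, peak_areas) {
  if (length(concentrations) < 3L || length(concentrations) != length(peak_areas))
    stop("need >= 3 calibration points with matching areas")
  if (stats::sd(concentrations) == 0) stop("degenerate design: all concentrations equal")
  fm <- stats::lm(peak_areas ~ concentrations)
  r2 <- if (stats::sd(peak_areas) == 0) 0 else stats::cor(concentrations, peak_areas)^2
  if (r2 < 0.99) warning(sprintf("standard curve r^2 = %.4f < 0.99", r2))
  structure(list(concentrations = concentrations, peak_areas = peak_areas,
                 slope = unname(stats::coef(fm)[2]),
                 intercept = unname(stats::coef(fm)[1]),
                 r_squared = r2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> area = %.4g + %.4g * conc (uM), r^2 = %.4f, %d points\n",
              x$intercept, x$slope, x$r_squared, length(x$concentrations)))
  invisible(x)
}

#' Quantify thiocyanate from a peak area
#'
#' Inverse prediction `(area - intercept) / slope`; negative predictions
#' are clamped to 0 with a warning.
#'
#' @param peak_area detector peak area(s).
#' @param curve a [fit_standard_curve()] result with positive slope.
#' @return concentration(s) in uM.
#' @export
quantify_scn <- function(peak_area, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope <= 0) stop("invalid standard curve: slope must be positive")
  conc <- (peak_area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative predicted concentration(s) clamped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}
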