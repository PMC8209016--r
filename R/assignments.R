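# Built-in serum 1H-NMR panel: 24 endogenous metabolites routinely resolved
# in rat serum CPMG spectra, with their assignment shifts and the cohort
# fold changes used as planted effects by the simulators.

serum_panel <- data.frame(
  name = c("Formate", "Cytidine", "Methylhistidine", "Histidine",
           "Phenylalanine", "Tyrosine", "Lactate", "Isoleucine",
           "Creatinine/creatinine phosphate", "Creatine", "Trimethylamine",
           "Methylguanidine", "Methionine", "Glutamine", "Acetoacetate",
           "Acetyl Groups (1)", "Acetyl Groups (2)", "Acetate", "Leucine",
           "Lipids (VLDL)", "Alanine", "Hydroxyisobutyrate", "Valine",
           "Lipids (LDL)"),
  shift_ppm = c(8.52, 7.80, 7.74, 7.71, 7.40, 7.17, 4.11, 3.65, 3.03, 3.00,
                2.91, 2.81, 2.64, 2.46, 2.22, 2.13, 2.06, 1.91, 1.72, 1.57,
                1.47, 1.08, 1.03, 0.87),
  # fold changes at 24 h: IR relative to sham within each supplementation arm,
  # and SCN/IR relative to vehicle/IR
  fold24_veh_IR_vs_sham = c(0.95, 0.93, 0.88, 0.98, 0.82, 0.89, 1.01, 0.95,
                            0.94, 0.95, 1.02, 1.08, 0.95, 0.98, 1.18, 0.96,
                            1.01, 0.83, 0.95, 1.23, 0.98, 1.02, 0.90, 1.04),
  fold24_scn_IR_vs_sham = c(1.41, 0.97, 1.08, 1.07, 1.09, 1.05, 1.01, 0.99,
                            1.13, 1.08, 1.06, 1.07, 1.07, 1.15, 0.84, 1.07,
                            1.02, 0.89, 1.09, 0.82, 1.08, 1.03, 1.02, 0.96),
  fold24_scn_IR_vs_veh_IR = c(1.02, 0.96, 0.95, 1.08, 0.94, 0.96, 1.11, 0.99,
                              0.95, 0.95, 1.00, 0.97, 0.98, 1.00, 1.05, 0.98,
                              1.03, 0.95, 0.97, 1.04, 1.04, 0.99, 0.99, 1.00),
  # fold changes at 4 weeks
  fold4w_veh_IR_vs_sham = c(0.76, 0.85, 0.94, 0.84, 0.99, 0.82, 1.05, 0.96,
                            0.85, 0.82, 0.88, 1.01, 0.95, 0.91, 1.08, 0.92,
                            0.95, 1.26, 0.89, 1.08, 0.94, 1.00, 0.99, 1.02),
  fold4w_scn_IR_vs_sham = c(1.00, 0.93, 0.86, 0.82, 0.96, 0.92, 1.05, 0.92,
                            0.90, 0.88, 0.98, 0.96, 0.97, 0.95, 1.16, 0.95,
                            0.98, 0.96, 0.90, 1.17, 0.92, 0.93, 0.98, 1.05),
  fold4w_scn_IR_vs_veh_IR = c(0.84, 0.91, 1.02, 0.97, 1.02, 0.90, 1.07, 1.08,
                              0.90, 0.91, 0.92, 1.05, 0.97, 0.94, 0.96, 0.93,
                              0.95, 1.09, 0.95, 0.96, 0.95, 1.02, 1.00, 0.97),
  stringsAsFactors = FALSE
)

#' Built-in serum metabolite assignment panel
#'
#' The 24-metabolite serum panel (formate at 8.52 ppm down to LDL lipids at
#' 0.87 ppm) used throughout the package, as a [metabolite_assignment()]
#' table.
#'
#' @param window_halfwidth_ppm integration half-width (ppm) attached to every
#'   assignment; default 0.02.
#' @return `metabolite_assignment` data.frame with 24 rows.
#' @export
serum_assignments <- function(window_halfwidth_ppm = 0.02) {
  metabolite_assignment(serum_panel$name, serum_panel$shift_ppm,
                        window_halfwidth_ppm)
}

#' Reference cohort fold changes for the serum panel
#'
#' Per-metabolite fold changes for the three standard group comparisons
#' (IR vs sham within the vehicle arm, IR vs sham within the thiocyanate
#' arm, and thiocyanate/IR vs vehicle/IR), at 24 h or 4 weeks after surgery.
#' These are the planted effects used by [generate_nmr_cohort()] defaults.
#'
#' @param timepoint `"24h"` or `"4w"`.
#' @return data.frame with columns `name`, `shift_ppm`,
#'   `veh_IR_vs_sham`, `scn_IR_vs_sham`, `scn_IR_vs_veh_IR`.
#' @export
serum_fold_changes <- function(timepoint = c("24h", "4w")) {
  timepoint <- match.arg(timepoint)
  pre <- if (timepoint == "24h") "fold24_" else "fold4w_"
  data.frame(
    name = serum_panel$name,
    shift_ppm = serum_panel$shift_ppm,
    veh_IR_vs_sham = serum_panel[[paste0(pre, "veh_IR_vs_sham")]],
    scn_IR_vs_sham = serum_panel[[paste0(pre, "scn_IR_vs_sham")]],
    scn_IR_vs_veh_IR = serum_panel[[paste0(pre, "scn_IR_vs_veh_IR")]],
    stringsAsFactors = FALSE
  )
}
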