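# CSV/JSON interchange for spectra, designs and generator truths.

#' Write a spectral cohort to a directory
#'
#' One 2-column CSV (`ppm`, `intensity`) per sample plus `design.csv`
#' (`sample_id`, `group`, `timepoint`) and, when supplied, the generator
#' truth as a JSON sidecar.
#'
#' @param spectra list of [spectrum1d()].
#' @param dir output directory (created).
#' @param truth optional `cohort_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_spectra_csv <- function(spectra, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in spectra)
    utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                     file.path(dir, paste0(s$sample_id, ".csv")), row.names = FALSE)
  design <- data.frame(
    sample_id = vapply(spectra, function(s) as.character(s$sample_id), character(1)),
    group = vapply(spectra, function(s) as.character(s$group), character(1)),
    timepoint = vapply(spectra, function(s) as.character(s$timepoint), character(1)))
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$metabolite_concentrations <- as.data.frame(tr$metabolite_concentrations)
    tr$design_means <- as.data.frame(tr$design_means)
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a spectral cohort from a directory
#'
#' @param dir directory produced by [write_spectra_csv()] (or hand-built to
#'   the same layout: per-sample `ppm,intensity` CSVs and a `design.csv`).
#' @return list of [spectrum1d()].
#' @export
read_spectra_csv <- function(dir) {
  design <- utils::read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(design)), function(i) {
    d <- utils::read.csv(file.path(dir, paste0(design$sample_id[i], ".csv")))
    spectrum1d(d$ppm, d$intensity, design$sample_id[i], design$group[i],
               design$timepoint[i])
  })
}
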