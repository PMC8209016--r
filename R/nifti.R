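# Minimal NIfTI-1 reader/writer.
#
# Covers single-file .nii / .nii.gz volumes with scalar datatypes (uint8,
# int16, int32, float32, float64), which is all this package emits or needs.
# Orientation handling is deliberately simple: voxel data are stored in the
# array order given (x fastest), pixdim carries the spacing, and a diagonal
# sform affine is written; a stored affine is returned as an attribute on
# read but not used to reorient.

nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param x 3-D numeric/logical array, a [volume_image()] or a [mask3d()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing in mm (ignored when `x` carries its own).
#' @param datatype `"float32"` (default for intensities) or `"uint8"`
#'   (default for logical masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), datatype = NULL) {
  if (inherits(x, "volume_image")) { spacing <- x$spacing; x <- x$intensities }
  if (inherits(x, "mask3d")) { spacing <- x$spacing; x <- x$voxels }
  if (is.logical(x)) { if (is.null(datatype)) datatype <- "uint8"; storage.mode(x) <- "integer" }
  if (is.null(datatype)) datatype <- "float32"
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  dt <- nifti_dtypes[[as.character(code)]]
  dm <- dim(x)
  if (length(dm) != 3L) stop("only 3-D volumes are supported")
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                                          # unused
  writeBin(as.integer(c(3L, dm, 1L, 1L, 1L, 1L)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                                          # intent etc.
  writeBin(as.integer(code), con, size = 2)                       # datatype
  writeBin(as.integer(8L * dt$size), con, size = 2)               # bitpix
  writeBin(0L, con, size = 2)                                     # slice_start
  writeBin(c(1, spacing, rep(0, 4)), con, size = 4)               # pixdim[8]
  writeBin(352, con, size = 4)                                    # vox_offset
  writeBin(c(1, 0), con, size = 4)                                # scl_slope/inter
  writeBin(raw(8), con)                                           # slice_end..cal_max
  writeBin(raw(20), con)                                          # cal_min..glmin
  writeBin(charToRaw(sprintf("%-80s", "irquant")), con)           # descrip
  writeBin(raw(24), con)                                          # aux_file
  writeBin(c(0L, 1L), con, size = 2)                              # qform, sform codes
  writeBin(rep(0, 6), con, size = 4)                              # quaternions/offsets
  srow <- rbind(c(spacing[1], 0, 0, 0), c(0, spacing[2], 0, 0), c(0, 0, spacing[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4)                    # srow_x/y/z
  writeBin(raw(16), con)                                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)                   # magic
  writeBin(raw(4), con)                                           # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(x), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return 3-D array with attributes `spacing` (mm) and `affine` (the sform
#'   rows, if present).
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  dimfield <- readBin(hdr[41:56], "integer", 8, size = 2, endian = endian)
  ndim <- dimfield[1]
  dm <- dimfield[2:(1 + max(ndim, 1))]
  code <- readBin(hdr[71:72], "integer", 1, size = 2, endian = endian)
  dt <- nifti_dtypes[[as.character(code)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", code)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = endian)
  scl <- readBin(hdr[113:120], "numeric", 2, size = 4, endian = endian)
  srow <- matrix(readBin(hdr[281:328], "numeric", 12, size = 4, endian = endian),
                 3, 4, byrow = TRUE)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dm)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed, endian = endian)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) vals <- vals * scl[1] + scl[2]
  arr <- array(vals, dim = dm)
  if (length(dm) > 3L) arr <- array(arr, dim = dm[1:3])  # drop singleton trailing dims
  attr(arr, "spacing") <- pixdim[2:4]
  attr(arr, "affine") <- srow
  arr
}

#' Read a NIfTI volume as a [volume_image()]
#' @param path file path.
#' @param contrast contrast tag for the returned object.
#' @return `volume_image`.
#' @export
read_volume_image <- function(path, contrast = c("T2STAR", "T1IR")) {
  arr <- read_nifti(path)
  volume_image(array(as.numeric(arr), dim = dim(arr)),
               spacing = attr(arr, "spacing"), contrast = match.arg(contrast))
}

#' Read a NIfTI mask as a [mask3d()]
#' @param path file path; non-zero voxels become TRUE.
#' @param label mask label.
#' @return `mask3d`.
#' @export
read_mask3d <- function(path, label = "LV") {
  arr <- read_nifti(path)
  mask3d(array(arr != 0, dim = dim(arr)), spacing = attr(arr, "spacing"), label = label)
}
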