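# Image file I/O. Fluorescence sections are 16-bit grayscale and are stored
# as PGM (P5), which round-trips integer grayscale exactly; trichrome
# sections are 8-bit RGB PNG via the png package. Pixel matrices follow the
# package convention [x, y] with x the fast axis.

#' Write a grayscale image as binary PGM (P5)
#'
#' @param img integer-valued matrix (values in `0..maxval`).
#' @param path output path.
#' @param maxval maximum grayscale value (255 for 8-bit, up to 65535;
#'   default 4095 for 12-bit fluorescence data).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 4095) {
  if (length(dim(img)) != 2L) stop("PGM requires a grayscale matrix")
  img <- round(img)
  if (min(img) < 0 || max(img) > maxval) stop("pixel values outside 0..maxval")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", nrow(img), ncol(img), maxval),
            con, eos = NULL)
  vals <- as.integer(img)  # raster order: x fastest, file rows = y
  if (maxval > 255) {
    writeBin(as.integer(vals), con, size = 2, endian = "big")
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a binary PGM (P5) image
#' @param path file path.
#' @return integer matrix `[x, y]` with attribute `maxval`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE); if (c2 == "\n") break } ; next }
    if (grepl("[[:space:]]", ch)) next
    cur <- ch
    repeat {
      c2 <- readChar(con, 1L, useBytes = TRUE)
      if (grepl("[[:space:]]", c2)) break
      cur <- paste0(cur, c2)
    }
    tok <- c(tok, cur)
  }
  if (tok[1] != "P5") stop("not a binary PGM file")
  nx <- as.integer(tok[2]); ny <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  n <- nx * ny
  vals <- if (maxval > 255) readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
          else as.integer(readBin(con, "raw", n))
  out <- t(matrix(vals, ny, nx, byrow = TRUE))
  attr(out, "maxval") <- maxval
  out
}

#' Write an 8-bit RGB image as PNG
#' @param img x-by-y-by-3 array with values 0-255 (or 0-1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) stop("need an RGB array")
  if (max(img) > 1) img <- img / 255
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}

#' Read an RGB PNG into the package pixel convention
#' @param path file path.
#' @return x-by-y-by-3 array with values 0-255.
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  round(aperm(a, c(2, 1, 3)) * 255)
}
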