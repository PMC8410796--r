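# Minimal binary PPM (P6) raster I/O.
#
# No PNG/JPEG codec is required at desk scale: the synthetic generator and
# the loaders speak PPM, a header plus raw RGB bytes. Arrays are H x W x 3
# with intensities in [0, 1].

#' Write an RGB raster as a binary PPM (P6) file
#'
#' @param img Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param path Output path (conventionally `.ppm`).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort("`img` must be a height x width x 3 array.",
          class = "melbalance_invalid_input")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pmin(pmax(img, 0), 1)
  # interleave channels per pixel, row-major as PPM requires
  rgb <- aperm(px, c(3, 2, 1))               # channel, col, row
  bytes <- as.raw(round(as.vector(rgb) * 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(bytes, con)
  invisible(path)
}

#' Read a binary PPM (P6) file
#'
#' @param path Path to a P6 PPM file.
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0); ch <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!identical(magic, "P6")) {
    abort(sprintf("Not a binary PPM (P6) file: %s", path),
          class = "melbalance_invalid_input")
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  bytes <- readBin(con, "raw", n = w * h * 3L)
  vals <- as.integer(bytes) / maxval
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}
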