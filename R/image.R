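#' 8-bit RGB image container
#'
#' An `rgb_image` is a plain numeric array of dimension `height x width x 3`
#' holding integer-valued intensities in \[0, 255\], channels ordered red,
#' green, blue. Coordinates are 0-based `(row, column)` in the exported API
#' documentation but standard 1-based R indexing applies to the array itself.
#' Grayscale input (a matrix, or an `H x W x 1` array) is replicated to three
#' identical channels.
#'
#' @param x a matrix (grayscale) or an `H x W x 3` (or `H x W x 1`) array of
#'   intensities in \[0, 255\].
#' @return a numeric `H x W x 3` array of class `rgb_image`.
#' @examples
#' img <- as_rgb_image(matrix(128, 8, 8))
#' dim(img)
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a matrix or an H x W x 3 array")
  if (dim(x)[3] == 1L) x <- array(x, c(dim(x)[1:2], 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(x)[3] != 3L) stop("expected 1, 3 or 4 channels, got ", dim(x)[3])
  if (any(dim(x)[1:2] < 1L)) stop("image must have positive dimensions")
  x <- array(round(as.numeric(x)), dim = dim(x))
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("intensities must lie in [0, 255]")
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  gray <- identical(x[, , 1], x[, , 2]) && identical(x[, , 1], x[, , 3])
  cat(sprintf("<rgb_image %d x %d, %s, range [%d, %d]>\n",
              d[1], d[2], if (gray) "gray" else "color", min(x), max(x)))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Test whether all three channels of an image are identical
#' @param image an [as_rgb_image()] array.
#' @return logical scalar.
#' @export
is_gray <- function(image) {
  identical(image[, , 1], image[, , 2]) && identical(image[, , 1], image[, , 3])
}

ext_of <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Load an image file as an 8-bit RGB array
#'
#' Supports PNG, TIFF and the portable anymap family (ASCII `P2`/`P3` and
#' binary `P5`/`P6` PGM/PPM). Grayscale files are replicated to three
#' channels; an alpha channel is dropped. Images with more than 8 bits per
#' sample are rejected: the filter bank and the 0/255 impulse rule are
#' defined on 8-bit data.
#'
#' @param path file path; format is chosen by extension
#'   (`png`, `tif`/`tiff`, `ppm`, `pgm`, `pnm`).
#' @return an [as_rgb_image()] array.
#' @seealso [save_image()]
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- ext_of(path)
  x <- switch(ext,
    png = {
      img <- png::readPNG(path, info = TRUE)
      info <- attr(img, "info")
      if (!is.null(info$bit.depth) && info$bit.depth > 8)
        stop(path, ": ", info$bit.depth,
             "-bit PNG not supported; convert to 8-bit first")
      img * 255
    },
    tif = ,
    tiff = {
      img <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(img, "bits.per.sample")
      if (!is.null(bits) && bits > 8)
        stop(path, ": ", bits,
             "-bit TIFF not supported; convert to 8-bit first")
      img * 255
    },
    ppm = ,
    pgm = ,
    pnm = read_pnm(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (supported: png, tiff, ppm, pgm)")
  )
  as_rgb_image(x)
}

#' Save an 8-bit RGB image losslessly
#'
#' PNG and TIFF are written through the corresponding packages; `pgm`/`ppm`
#' are written as binary `P5`/`P6`. Saving to `pgm` requires all three
#' channels to be identical (the file keeps one channel on disk). Lossy
#' formats are refused so that `load_image(save_image(x)) == x` always holds.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  image <- as_rgb_image(image)
  ext <- ext_of(path)
  if (ext %in% c("jpg", "jpeg"))
    stop("refusing lossy format '", ext, "'; use png, tiff, ppm or pgm")
  switch(ext,
    png = png::writePNG(image / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(image / 255, path, bits.per.sample = 8L,
                           compression = "none"),
    ppm = write_pnm(image, path, gray = FALSE),
    pgm = {
      if (!is_gray(image))
        stop("pgm is single-channel; image has unequal channels")
      write_pnm(image, path, gray = TRUE)
    },
    stop("unsupported image format '", ext, "' for ", path)
  )
  invisible(path)
}

# Minimal PGM/PPM (P2/P3 ASCII, P5/P6 binary) reader; maxval must be < 256.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # read header tokens, skipping '#' comments
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop(path, ": truncated PNM header")
      if (grepl("^\\s$", ch)) next
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || grepl("^\\s$", ch)) break
        tok <- paste0(tok, ch)
      }
      return(tok)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop(path, ": unsupported PNM magic '", magic, "'")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || is.na(maxval)) stop(path, ": bad PNM header")
  if (maxval > 255)
    stop(path, ": maxval ", maxval, " (> 8 bit) not supported")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    v <- suppressWarnings(as.numeric(strsplit(trimws(rest), "\\s+")[[1]]))
    if (length(v) < n || anyNA(v[seq_len(n)]))
      stop(path, ": bad ASCII PNM data")
    v[seq_len(n)]
  }
  if (length(vals) < n) stop(path, ": truncated PNM data")
  # raster order: rows top to bottom, channels interleaved per pixel
  arr <- array(0, c(h, w, nch))
  for (ch in seq_len(nch))
    arr[, , ch] <- matrix(vals[seq(ch, n, by = nch)], h, w, byrow = TRUE)
  arr
}

write_pnm <- function(image, path, gray) {
  h <- dim(image)[1]; w <- dim(image)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", if (gray) "P5" else "P6", w, h),
            con, eos = NULL)
  if (gray) {
    vals <- as.integer(t(image[, , 1]))
  } else {
    # interleave channels pixel-by-pixel in raster order
    vals <- integer(h * w * 3L)
    for (ch in 1:3)
      vals[seq(ch, length(vals), by = 3L)] <- as.integer(t(image[, , ch]))
  }
  writeBin(as.raw(vals), con)
}
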