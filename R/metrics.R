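#' Peak signal-to-noise ratio between two 8-bit images
#'
#' Per-channel mean squared error, channel-averaged MSE, and
#' `PSNR = 10 * log10(255^2 / MSE)` in decibels. Identical images have
#' `MSE = 0`; their PSNR is reported as the `Inf` sentinel rather than a
#' finite overflow value.
#'
#' @param original,filtered two [as_rgb_image()] arrays (or coercible
#'   inputs) of equal size.
#' @return a list of class `quality_scores` with `psnr_db`, `mse` and
#'   `mse_per_channel` (named r/g/b).
#' @examples
#' a <- as_rgb_image(matrix(0, 16, 16))
#' b <- as_rgb_image(matrix(255, 16, 16))
#' psnr(a, b)$psnr_db   # 0 dB: the worst case for 8-bit data
#' @export
psnr <- function(original, filtered) {
  original <- as_rgb_image(original); filtered <- as_rgb_image(filtered)
  if (!all(dim(original) == dim(filtered)))
    stop("image dimensions differ: ", paste(dim(original), collapse = "x"),
         " vs ", paste(dim(filtered), collapse = "x"))
  mse_ch <- vapply(1:3, function(ch) {
    mean((original[, , ch] - filtered[, , ch])^2)
  }, 0)
  names(mse_ch) <- c("r", "g", "b")
  mse <- mean(mse_ch)
  structure(list(
    psnr_db = if (mse == 0) Inf else 10 * log10(255^2 / mse),
    mse = mse, mse_per_channel = mse_ch), class = "quality_scores")
}

#' @export
print.quality_scores <- function(x, ...) {
  cat(sprintf("PSNR: %s dB  (MSE %.4f; r %.4f, g %.4f, b %.4f)\n",
              if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.4f", x$psnr_db),
              x$mse, x$mse_per_channel["r"], x$mse_per_channel["g"],
              x$mse_per_channel["b"]))
  invisible(x)
}

#' Analog BT.601 RGB to YUV conversion
#'
#' Unquantized linear transform: `Y = 0.299 R + 0.587 G + 0.114 B`,
#' `U = 0.492 (B - Y)`, `V = 0.877 (R - Y)`. Gray pixels have zero
#' chrominance. The coefficient set is exposed as the `matrix` attribute so
#' an alternate convention can be verified against it.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @return an `H x W x 3` numeric array, planes Y, U, V.
#' @export
rgb_to_yuv <- function(image) {
  image <- as_rgb_image(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  out <- array(c(Y, 0.492 * (B - Y), 0.877 * (R - Y)), dim = dim(image))
  attr(out, "matrix") <- "BT.601 analog (0.492 / 0.877 chroma scaling)"
  out
}

#' Normalized color difference in YUV space
#'
#' `NCD = sum ||(Y,U,V) - (Yc,Uc,Vc)|| / sum ||(Y,U,V)||` with Euclidean
#' norms per pixel, summed over the image: 0 for identical images, exactly
#' 1 when the filtered image is all black. Lower is better. Not symmetric
#' in its arguments (the denominator is the original's color magnitude).
#'
#' @param original reference image; must not be entirely black.
#' @param filtered image under test, same size.
#' @return nonnegative scalar.
#' @export
ncd <- function(original, filtered) {
  original <- as_rgb_image(original); filtered <- as_rgb_image(filtered)
  if (!all(dim(original) == dim(filtered)))
    stop("image dimensions differ")
  a <- rgb_to_yuv(original); b <- rgb_to_yuv(filtered)
  num <- sum(sqrt((a[, , 1] - b[, , 1])^2 + (a[, , 2] - b[, , 2])^2 +
                  (a[, , 3] - b[, , 3])^2))
  den <- sum(sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2))
  if (den == 0)
    stop("NCD undefined: original image is entirely black (zero denominator)")
  num / den
}
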