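#' Two-round modified Laplacian vector median filter
#'
#' The full denoising pipeline. Round one scans the input with the
#' first-round directional Laplacian bank (K1-K8), declares impulses by the
#' minimum-variation threshold plus 0/255 rule, and replaces them with
#' their 3x3 vector median, giving the intermediate image Ic. Round two
#' scans Ic with the direct-neighbor-blind bank (K9-K16) -- which sees past
#' clusters of equal-valued impulses that blind the first round -- and
#' replaces its detections the same way. Exactly two rounds are run; pixels
#' never flagged in either round pass through byte-identical.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param threshold variation threshold applied identically in both rounds;
#'   default 75 on the raw integer-kernel response scale.
#' @param norm `"L1"` or `"L2"` distance for the vector median.
#' @param border border policy for the convolutions, see [convolve_abs()].
#' @param bank kernel bank, normally [build_kernel_bank()].
#' @return a list of class `mlvmf_result`:
#'   \describe{
#'     \item{restored}{the final image.}
#'     \item{intermediate}{Ic, the image after round one.}
#'     \item{mask_round1, mask_round2}{`mlvmf_mask` objects.}
#'     \item{counts}{named integer vector of flagged pixels per round.}
#'     \item{threshold, norm, border, kernel_checksum}{run provenance.}
#'   }
#' @examples
#' ph <- make_phantom("flat", 32, 32)
#' rec <- plant_collision(ph, rbind(c(10, 10)), 255)
#' res <- mlvmf(rec$noisy)
#' res$counts
#' @export
mlvmf <- function(image, threshold = 75, norm = c("L1", "L2"),
                  border = "replicate", bank = build_kernel_bank()) {
  image <- as_rgb_image(image)
  norm <- match.arg(norm)
  m1 <- min_variation(variation_tensor(image, bank, "first", border))
  mask1 <- detect_impulses(image, m1, threshold)
  ic <- vmf_replace(image, mask1, norm)
  m2 <- min_variation(variation_tensor(ic, bank, "second", border))
  mask2 <- detect_impulses(ic, m2, threshold)
  restored <- vmf_replace(ic, mask2, norm)
  structure(list(
    restored = restored, intermediate = ic,
    mask_round1 = mask1, mask_round2 = mask2,
    counts = c(round1 = sum(mask1$flagged), round2 = sum(mask2$flagged)),
    threshold = threshold, norm = norm, border = border,
    kernel_checksum = kernel_bank_checksum(bank)),
    class = "mlvmf_result")
}

#' @export
print.mlvmf_result <- function(x, ...) {
  d <- dim(x$restored)
  cat(sprintf("<mlvmf_result: %d x %d image, T = %g, %s norm>\n",
              d[1], d[2], x$threshold, x$norm))
  cat(sprintf("  flagged: %d (round 1) + %d (round 2)\n",
              x$counts["round1"], x$counts["round2"]))
  invisible(x)
}

#' @export
summary.mlvmf_result <- function(object, ...) {
  print(object)
  cat(sprintf("  border policy: %s\n  kernel bank: %s\n",
              object$border, object$kernel_checksum))
  invisible(object)
}

#' Benchmark filters over noise levels and seeds
#'
#' For every (image, noise level, seed) combination the clean image is
#' corrupted with monochrome salt-and-pepper noise, each requested filter
#' is run, and PSNR/NCD against the clean image are recorded. `"identity"`
#' scores the noisy image itself (the lower baseline), `"vmf"` is the
#' whole-image 3x3 vector median, `"mlvmf"` the two-round filter.
#'
#' @param clean_images named list of [as_rgb_image()] arrays (names become
#'   the `image` column).
#' @param noise_levels numeric vector of percentages.
#' @param filters character vector from `"mlvmf"`, `"vmf"`, `"identity"`.
#' @param seeds integer vector of noise seeds.
#' @param threshold,norm passed to [mlvmf()].
#' @return a data.frame with columns image, noise, filter, psnr_db, ncd,
#'   seed, sorted by (image, noise, filter, seed). A zero-MSE case yields
#'   `psnr_db = Inf` (written as the string `"Inf"` if saved to CSV).
#' @export
evaluate_filters <- function(clean_images, noise_levels, filters, seeds,
                             threshold = 75, norm = "L1") {
  stopifnot(length(clean_images) > 0, length(noise_levels) > 0,
            length(filters) > 0, length(seeds) > 0)
  known <- c("mlvmf", "vmf", "identity")
  bad <- setdiff(filters, known)
  if (length(bad) > 0)
    stop("unknown filter name: ", paste(bad, collapse = ", "))
  if (is.null(names(clean_images)))
    names(clean_images) <- paste0("image", seq_along(clean_images))
  bank <- build_kernel_bank()
  rows <- list()
  for (img_name in sort(names(clean_images))) {
    clean <- as_rgb_image(clean_images[[img_name]])
    for (level in sort(noise_levels)) {
      for (seed in seeds) {
        noisy <- add_salt_pepper(clean,
                                 noise_spec(level, seed = seed))$noisy
        for (f in sort(filters)) {
          out <- switch(f,
            identity = noisy,
            vmf = vmf_full(noisy, norm),
            mlvmf = mlvmf(noisy, threshold, norm, bank = bank)$restored)
          rows[[length(rows) + 1L]] <- data.frame(
            image = img_name, noise = level, filter = f,
            psnr_db = psnr(clean, out)$psnr_db,
            ncd = ncd(clean, out), seed = seed,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$image, out$noise, out$filter, out$seed), , drop = FALSE]
}
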