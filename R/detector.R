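pad_replicate <- function(mat, k) {
  n <- nrow(mat); m <- ncol(mat)
  mat[c(rep(1L, k), seq_len(n), rep(n, k)),
      c(rep(1L, k), seq_len(m), rep(m, k))]
}

#' Absolute convolution response of one kernel on one channel
#'
#' Computes `|sum_{u,v} kernel[u,v] * channel[x+u-2, y+v-2]|` at every
#' pixel. Arithmetic is exact: integer weights times 8-bit intensities,
#' absolute value taken last. Under the `"replicate"` border policy edge
#' pixels are extended outward so every pixel, including borders, gets a
#' response.
#'
#' @param channel a numeric matrix of intensities.
#' @param kernel an `mlvmf_kernel` (or any odd-sized numeric matrix).
#' @param border `"replicate"` (edge extension) or `"zero"`.
#' @return a nonnegative numeric matrix of the same size as `channel`.
#' @export
convolve_abs <- function(channel, kernel, border = c("replicate", "zero")) {
  border <- match.arg(border)
  w <- if (inherits(kernel, "mlvmf_kernel")) kernel$weights else kernel
  if (nrow(w) != ncol(w) || nrow(w) %% 2 == 0)
    stop("kernel must be a square odd-sized stencil")
  k <- (nrow(w) - 1L) %/% 2L
  n <- nrow(channel); m <- ncol(channel)
  pad <- if (border == "replicate") pad_replicate(channel, k) else {
    z <- matrix(0, n + 2L * k, m + 2L * k)
    z[k + seq_len(n), k + seq_len(m)] <- channel
    z
  }
  out <- matrix(0, n, m)
  nz <- which(w != 0, arr.ind = TRUE)
  for (t in seq_len(nrow(nz))) {
    du <- nz[t, 1] - (k + 1L); dv <- nz[t, 2] - (k + 1L)
    out <- out + w[nz[t, 1], nz[t, 2]] *
      pad[k + seq_len(n) + du, k + seq_len(m) + dv]
  }
  abs(out)
}

#' Stack of variation measurements for one detection round
#'
#' Applies the round's 8 kernels to each of the 3 color channels, giving 24
#' absolute-response planes per pixel.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param bank a [build_kernel_bank()] object.
#' @param round `"first"` (K1-K8) or `"second"` (K9-K16).
#' @param border border policy, see [convolve_abs()].
#' @return an `mlvmf_variation` object: an `H x W x 8 x 3` array (kernel
#'   index in round order, channel index r/g/b) with attributes
#'   `kernel_ids` and `round`.
#' @export
variation_tensor <- function(image, bank = build_kernel_bank(),
                             round = c("first", "second"),
                             border = "replicate") {
  image <- as_rgb_image(image)
  round <- match.arg(round)
  ks <- round_kernels(bank, round)
  n <- dim(image)[1]; m <- dim(image)[2]
  v <- array(0, c(n, m, 8L, 3L))
  for (i in seq_along(ks))
    for (j in 1:3)
      v[, , i, j] <- convolve_abs(image[, , j], ks[[i]], border)
  structure(v, kernel_ids = names(ks), round = round,
            class = "mlvmf_variation")
}

#' Per-pixel minimum over the 24 variation measurements
#'
#' For each pixel, the minimum response across the round's 8 kernels and 3
#' channels, with the attaining (kernel, channel) pair. Ties resolve to the
#' smallest (kernel id, channel id) pair in id order, so the result is
#' deterministic.
#'
#' @param tensor an `mlvmf_variation` from [variation_tensor()].
#' @return a list of class `mlvmf_minmap` with fields `M` (numeric matrix),
#'   `argmin_kernel` (integer matrix, 1-8 within the round),
#'   `argmin_channel` (integer matrix, 1=red, 2=green, 3=blue),
#'   `kernel_ids`, `round`.
#' @export
min_variation <- function(tensor) {
  stopifnot(inherits(tensor, "mlvmf_variation"))
  d <- dim(tensor)
  M <- matrix(Inf, d[1], d[2])
  argk <- argj <- matrix(1L, d[1], d[2])
  for (i in seq_len(d[3])) {
    for (j in seq_len(d[4])) {
      plane <- tensor[, , i, j]
      upd <- plane < M          # strict: first (kernel, channel) pair wins ties
      M[upd] <- plane[upd]
      argk[upd] <- i
      argj[upd] <- j
    }
  }
  structure(list(M = M, argmin_kernel = argk, argmin_channel = argj,
                 kernel_ids = attr(tensor, "kernel_ids"),
                 round = attr(tensor, "round")),
            class = "mlvmf_minmap")
}

#' Threshold + extreme-value impulse declaration
#'
#' A pixel is declared an impulse when its minimum variation exceeds the
#' threshold AND its intensity on the minimizing channel -- read from the
#' image the round's tensor was computed on -- is exactly 0 or 255. The
#' second test is what makes the filter "switching": high-variation pixels
#' at non-extreme values (true edges, texture) pass through untouched.
#'
#' @param image the round-input [as_rgb_image()] array the minima were
#'   computed from.
#' @param minmap an `mlvmf_minmap` from [min_variation()].
#' @param threshold nonnegative response threshold on the raw (unnormalized
#'   integer kernel) scale; default 75.
#' @return a list of class `mlvmf_mask` with fields `flagged` (logical
#'   matrix), `round`, `threshold_used`.
#' @export
detect_impulses <- function(image, minmap, threshold = 75) {
  image <- as_rgb_image(image)
  stopifnot(inherits(minmap, "mlvmf_minmap"), threshold >= 0)
  n <- dim(image)[1]; m <- dim(image)[2]
  if (!all(dim(minmap$M) == c(n, m)))
    stop("minmap size does not match image")
  idx <- cbind(rep(seq_len(n), m), rep(seq_len(m), each = n),
               as.vector(minmap$argmin_channel))
  at_min_channel <- matrix(image[idx], n, m)
  flagged <- (minmap$M > threshold) & (at_min_channel %in% c(0, 255))
  structure(list(flagged = flagged, round = minmap$round,
                 threshold_used = threshold),
            class = "mlvmf_mask")
}

#' @export
print.mlvmf_mask <- function(x, ...) {
  cat(sprintf("<mlvmf_mask: %d flagged pixels (round %s, T = %g)>\n",
              sum(x$flagged), x$round, x$threshold_used))
  invisible(x)
}
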