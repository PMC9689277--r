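#' Vector median of a set of RGB vectors
#'
#' The vector median is the member of the window minimizing the sum of
#' distances (L1 city-block by default, or L2 Euclidean) to all other
#' members; the output is always an existing window color, never an
#' invented one. Ties resolve to the earliest vector in the given order
#' (raster order when the window comes from a 3x3 neighborhood).
#'
#' @param window a `k x 3` numeric matrix of RGB vectors, `k >= 1`.
#' @param norm `"L1"` or `"L2"`.
#' @return a length-3 numeric RGB vector, one of the rows of `window`.
#' @examples
#' w <- rbind(matrix(10, 8, 3), c(255, 255, 255))
#' vector_median(w)
#' @export
vector_median <- function(window, norm = c("L1", "L2")) {
  norm <- match.arg(norm)
  window <- matrix(window, ncol = 3)
  k <- nrow(window)
  if (k < 1) stop("empty window")
  D <- numeric(k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      d <- if (norm == "L1") sum(abs(window[a, ] - window[b, ]))
           else sqrt(sum((window[a, ] - window[b, ])^2))
      D[a] <- D[a] + d
      D[b] <- D[b] + d
    }
  }
  window[which.min(D), ]
}

# Vectorized 3x3 vector-median at the given 1-based pixel rows/cols.
# Returns an npix x 3 matrix of replacement vectors. Windows are read from
# `image` with replicate padding; candidate order is raster order, center
# included, ties to the earliest candidate.
vmf_at <- function(image, rows, cols, norm) {
  n <- dim(image)[1]; m <- dim(image)[2]
  pad <- array(0, c(n + 2L, m + 2L, 3L))
  for (ch in 1:3) pad[, , ch] <- pad_replicate(image[, , ch], 1L)
  np <- length(rows)
  V <- array(0, c(np, 9L, 3L))
  o <- 0L
  for (dr in -1:1) {
    for (dc in -1:1) {
      o <- o + 1L
      for (ch in 1:3)
        V[, o, ch] <- pad[cbind(rows + 1L + dr, cols + 1L + dc, ch)]
    }
  }
  D <- matrix(0, np, 9L)
  for (a in 1:8) {
    for (b in (a + 1):9) {
      if (norm == "L1") {
        d <- abs(V[, a, 1] - V[, b, 1]) + abs(V[, a, 2] - V[, b, 2]) +
             abs(V[, a, 3] - V[, b, 3])
      } else {
        d <- sqrt((V[, a, 1] - V[, b, 1])^2 + (V[, a, 2] - V[, b, 2])^2 +
                  (V[, a, 3] - V[, b, 3])^2)
      }
      D[, a] <- D[, a] + d
      D[, b] <- D[, b] + d
    }
  }
  sel <- max.col(-D, ties.method = "first")
  cbind(V[cbind(seq_len(np), sel, 1L)],
        V[cbind(seq_len(np), sel, 2L)],
        V[cbind(seq_len(np), sel, 3L)])
}

#' Replace flagged pixels by their 3x3 vector median
#'
#' Batch semantics: every replacement is computed from the *input* image
#' before any pixel is written, so the result does not depend on scan
#' order. Unflagged pixels are byte-identical to the input.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param mask an `mlvmf_mask` from [detect_impulses()], or a logical
#'   matrix of the image size.
#' @param norm `"L1"` or `"L2"`.
#' @return the filtered [as_rgb_image()].
#' @export
vmf_replace <- function(image, mask, norm = c("L1", "L2")) {
  image <- as_rgb_image(image)
  norm <- match.arg(norm)
  flagged <- if (inherits(mask, "mlvmf_mask")) mask$flagged else mask
  if (!is.logical(flagged) || !all(dim(flagged) == dim(image)[1:2]))
    stop("mask size does not match image")
  if (!any(flagged)) return(image)
  # which(..., arr.ind) lists positions in column-major order, matching the
  # order logical-matrix assignment writes them back
  pos <- which(flagged, arr.ind = TRUE)
  rep_vec <- vmf_at(image, pos[, 1], pos[, 2], norm)
  out <- image
  for (ch in 1:3) out[, , ch][flagged] <- rep_vec[, ch]
  out
}

#' Whole-image 3x3 vector median filter
#'
#' The classic vector median baseline: every pixel is replaced by the
#' vector median of its 3x3 neighborhood (batch semantics, replicate
#' borders).
#'
#' @inheritParams vmf_replace
#' @return the filtered [as_rgb_image()].
#' @export
vmf_full <- function(image, norm = c("L1", "L2")) {
  image <- as_rgb_image(image)
  norm <- match.arg(norm)
  n <- dim(image)[1]; m <- dim(image)[2]
  rows <- rep(seq_len(n), m)
  cols <- rep(seq_len(m), each = n)
  rep_vec <- vmf_at(image, rows, cols, norm)
  out <- image
  for (ch in 1:3) out[, , ch] <- matrix(rep_vec[, ch], n, m)
  out
}
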