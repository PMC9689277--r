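# run expr with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a salt-and-pepper corruption
#'
#' @param percentage fraction of corrupted samples, in percent (0-100).
#' @param salt_fraction share of impulses set to 255 ("salt"); the rest
#'   become 0 ("pepper"). Default 0.5, the conventional even split.
#' @param mode `"monochrome"` draws one corruption decision per pixel and
#'   sets all three channels to the same impulse value (the natural model
#'   for grayscale radiographs); `"channelwise"` draws independently per
#'   channel sample (the natural model for color transmission errors).
#' @param seed integer driving the pseudo-random draws; identical spec +
#'   seed yields an identical corruption.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(percentage, salt_fraction = 0.5,
                       mode = c("monochrome", "channelwise"), seed = 1L) {
  if (!is.numeric(percentage) || length(percentage) != 1 ||
      is.na(percentage) || percentage < 0 || percentage > 100)
    stop("percentage must be a single value in [0, 100]")
  if (salt_fraction < 0 || salt_fraction > 1)
    stop("salt_fraction must lie in [0, 1]")
  structure(list(percentage = percentage, salt_fraction = salt_fraction,
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Inject salt-and-pepper impulse noise with ground truth
#'
#' Each pixel (monochrome mode) or each channel sample (channelwise mode)
#' is independently replaced with probability `percentage/100`; a corrupted
#' sample becomes 255 with probability `salt_fraction`, else 0. The
#' returned masks record the ground truth: positions whose stored value
#' actually changed (a "corruption" that re-wrote an existing 0 or 255 with
#' the same value alters nothing and is not flagged), so the noisy and
#' clean images differ exactly on the mask.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param spec a [noise_spec()].
#' @return a list of class `corruption_record` with fields `noisy`
#'   (rgb_image), `truth_mask` (H x W logical: corrupted in any channel),
#'   `per_channel_mask` (H x W x 3 logical), `spec`, and `realized_fraction`
#'   (share of pixels, or samples in channelwise mode, actually altered).
#' @examples
#' rec <- add_salt_pepper(make_phantom("flat", 32, 32), noise_spec(10, seed = 7))
#' mean(rec$truth_mask)
#' @export
add_salt_pepper <- function(image, spec) {
  image <- as_rgb_image(image)
  stopifnot(inherits(spec, "noise_spec"))
  n <- dim(image)[1]; m <- dim(image)[2]
  p <- spec$percentage / 100
  noisy <- image
  with_seed(spec$seed, {
    if (spec$mode == "monochrome") {
      hit <- matrix(stats::runif(n * m) < p, n, m)
      val <- matrix(ifelse(stats::runif(n * m) < spec$salt_fraction, 255, 0),
                    n, m)
      for (ch in 1:3) noisy[, , ch][hit] <- val[hit]
    } else {
      hit <- array(stats::runif(n * m * 3) < p, c(n, m, 3))
      val <- array(ifelse(stats::runif(n * m * 3) < spec$salt_fraction,
                          255, 0), c(n, m, 3))
      noisy[hit] <- val[hit]
    }
  })
  per_channel <- array(noisy != image, c(n, m, 3))
  truth <- per_channel[, , 1] | per_channel[, , 2] | per_channel[, , 3]
  realized <- if (spec$mode == "monochrome") mean(truth) else mean(per_channel)
  structure(list(noisy = noisy, truth_mask = truth,
                 per_channel_mask = per_channel, spec = spec,
                 realized_fraction = realized),
            class = "corruption_record")
}

#' @export
print.corruption_record <- function(x, ...) {
  cat(sprintf(
    "<corruption_record: %d/%d pixels corrupted (%.2f%%), mode %s, seed %d>\n",
    sum(x$truth_mask), length(x$truth_mask), 100 * mean(x$truth_mask),
    x$spec$mode, x$spec$seed))
  invisible(x)
}

#' Plant a deterministic cluster of same-valued impulses
#'
#' Sets exactly the listed pixels (all three channels) to a single impulse
#' value. Used to build 4-/8-connected impulse "collisions" -- clusters of
#' equal-valued impulses that hide each other from neighbor-based
#' detectors -- at known positions.
#'
#' @param image an [as_rgb_image()] array (or coercible input).
#' @param positions two-column matrix (or list of length-2 vectors) of
#'   0-based `(row, col)` coordinates.
#' @param value 0 or 255.
#' @return a `corruption_record`; the masks mark exactly `positions`.
#' @export
plant_collision <- function(image, positions, value) {
  image <- as_rgb_image(image)
  if (!value %in% c(0, 255)) stop("value must be 0 or 255")
  if (is.list(positions)) positions <- do.call(rbind, positions)
  positions <- matrix(as.integer(positions), ncol = 2)
  n <- dim(image)[1]; m <- dim(image)[2]
  truth <- matrix(FALSE, n, m)
  noisy <- image
  if (nrow(positions) > 0) {
    if (any(positions[, 1] < 0 | positions[, 1] >= n |
            positions[, 2] < 0 | positions[, 2] >= m))
      stop("position outside the image")
    idx <- cbind(positions[, 1] + 1L, positions[, 2] + 1L)
    truth[idx] <- TRUE
    for (ch in 1:3) noisy[, , ch][truth] <- value
  }
  structure(list(noisy = noisy, truth_mask = truth,
                 per_channel_mask = array(truth, c(n, m, 3)),
                 spec = NULL, realized_fraction = mean(truth)),
            class = "corruption_record")
}

#' Piecewise-smooth phantom test images
#'
#' Synthetic stand-ins for the usual 8-bit test photographs and chest
#' radiographs. All phantoms are grayscale replicated to RGB, with
#' intensities kept inside \[1, 254\] so every planted 0/255 impulse
#' differs from the clean value.
#'
#' * `flat`: a constant plane (value 128).
#' * `gradient`: a smooth diagonal ramp, 30 to 220.
#' * `blocks`: a 4x4 grid of constant tiles from the palette
#'   {40, 100, 160, 220} arranged so every step edge is at least 60 levels.
#' * `chest_like`: a chest-radiograph-like scene -- vertical gradient
#'   background, two dark elliptical lung fields, bright rib-like arcs and
#'   a bright central mediastinum column, with mild seeded smooth
#'   illumination variation.
#'
#' @param kind one of `"flat"`, `"gradient"`, `"blocks"`, `"chest_like"`.
#' @param height,width image size in pixels, each at least 16.
#' @param seed integer; `chest_like` uses it for the illumination field,
#'   the other kinds are fully deterministic.
#' @return an [as_rgb_image()] array.
#' @examples
#' ph <- make_phantom("blocks", 64, 64)
#' range(ph)
#' @export
make_phantom <- function(kind = c("flat", "gradient", "blocks", "chest_like"),
                         height, width, seed = 1L) {
  kind <- match.arg(kind)
  if (height < 16 || width < 16) stop("height and width must be >= 16")
  n <- as.integer(height); m <- as.integer(width)
  g <- switch(kind,
    flat = matrix(128, n, m),
    gradient = {
      r <- matrix(seq(0, 1, length.out = n), n, m)
      c_ <- matrix(seq(0, 1, length.out = m), n, m, byrow = TRUE)
      30 + 190 * (r + c_) / 2
    },
    blocks = {
      palette <- c(40, 100, 160, 220)
      ti <- pmin(((seq_len(n) - 1L) * 4L) %/% n, 3L)
      tj <- pmin(((seq_len(m) - 1L) * 4L) %/% m, 3L)
      idx <- outer(ti, tj, function(a, b) (a + b) %% 4L)
      matrix(palette[idx + 1L], n, m)
    },
    chest_like = chest_phantom(n, m, seed)
  )
  g <- pmin(pmax(round(g), 1), 254)
  as_rgb_image(g)
}

chest_phantom <- function(n, m, seed) {
  r <- matrix(seq_len(n), n, m)
  c_ <- matrix(seq_len(m), n, m, byrow = TRUE)
  bg <- 90 + 60 * (r - 1) / (n - 1)              # vertical gradient 90..150
  inside_ellipse <- function(cr, cc, ar, ac) {
    ((r - cr) / ar)^2 + ((c_ - cc) / ac)^2 <= 1
  }
  img <- bg
  # mediastinum: bright central column
  img[abs(c_ - m / 2) < m * 0.08] <- 200
  # two dark lung fields
  lungs <- inside_ellipse(n * 0.45, m * 0.30, n * 0.30, m * 0.16) |
           inside_ellipse(n * 0.45, m * 0.70, n * 0.30, m * 0.16)
  img[lungs] <- 45
  # rib-like bright arcs: thin elliptical annuli crossing the lung fields
  for (k in 1:4) {
    cr <- n * (0.18 + 0.16 * k)
    band <- abs(((r - cr) / (n * 0.06))^2 + ((c_ - m / 2) / (m * 0.45))^2 - 1)
    img[band < 0.08 & lungs] <- 170
  }
  # mild smooth seeded illumination variation (low-frequency cosines)
  with_seed(seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 3, 8)
    img <- img + amp * cos(2 * pi * (r - 1) / n + ph[1]) *
                 cos(2 * pi * (c_ - 1) / m + ph[2])
  })
  img
}
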