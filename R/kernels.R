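#' Directional Laplacian kernel banks
#'
#' The detector measures local intensity variation with two banks of eight
#' 5x5 zero-sum stencils, one bank per detection round. Each kernel places
#' negative unit weights on the lattice cells that best approximate the line
#' through the center at its nominal direction (multiples of pi/8), with a
#' positive center weight equal to the number of negative cells, so every
#' kernel responds zero on constant and on linear-ramp patches and strongly
#' on isolated outliers.
#'
#' First-round kernels (K1-K8) use cells at Chebyshev distance 1 and 2.
#' Second-round kernels (K9-K16) are restricted to the outer ring at
#' Chebyshev distance 2: the eight direct neighbors of the center carry
#' weight exactly 0, so a pixel whose whole 8-neighborhood is corrupted at
#' the same impulse value is still compared against clean pixels. Weights
#' are integers and unnormalized; the detection threshold is expressed on
#' this raw response scale.
#'
#' @name kernel_bank
NULL

# offsets as (dr, dc) pairs, rows of a matrix; center weight = nrow(offsets)
kernel_from_offsets <- function(id, offsets, round, angle) {
  w <- matrix(0L, 5L, 5L)
  for (k in seq_len(nrow(offsets)))
    w[offsets[k, 1] + 3L, offsets[k, 2] + 3L] <- -1L
  w[3L, 3L] <- nrow(offsets)
  structure(list(id = id, weights = w, round = round, angle = angle),
            class = "mlvmf_kernel")
}

#' @export
print.mlvmf_kernel <- function(x, ...) {
  cat(sprintf("%s  (round %s, angle %s*pi/8)\n", x$id,
              if (x$round == "first") 1 else 2,
              format(x$angle / (pi / 8))))
  m <- format(x$weights, width = 3)
  for (i in 1:5) cat(" ", paste(m[i, ], collapse = " "), "\n")
  invisible(x)
}

# (dr, dc) offsets of the negative cells for each nominal direction.
# Full (both-radius) version used by round one; round two keeps only the
# Chebyshev-distance-2 cells.
direction_offsets <- function() {
  list(
    `0`     = rbind(c(0, -2), c(0, -1), c(0, 1), c(0, 2)),
    `pi/4`  = rbind(c(-2, 2), c(-1, 1), c(1, -1), c(2, -2)),
    `pi/2`  = rbind(c(-2, 0), c(-1, 0), c(1, 0), c(2, 0)),
    `3pi/4` = rbind(c(-2, -2), c(-1, -1), c(1, 1), c(2, 2)),
    `pi/8`  = rbind(c(0, -1), c(0, 1), c(-1, 2), c(1, -2)),
    `3pi/8` = rbind(c(-1, 0), c(1, 0), c(-2, 1), c(2, -1)),
    `5pi/8` = rbind(c(-1, 0), c(1, 0), c(-2, -1), c(2, 1)),
    `7pi/8` = rbind(c(0, -1), c(0, 1), c(-1, -2), c(1, 2))
  )
}

#' Build the 16-kernel directional Laplacian bank
#'
#' Returns the full bank: K1-K8 (round one, directions 0, pi/4, pi/2,
#' 3pi/4, pi/8, 3pi/8, 5pi/8, 7pi/8) and K9-K16 (round two, same
#' directions, outer ring only). The list order is the kernel id order and
#' is the tie-break order of the detector's argmin.
#'
#' @return an object of class `mlvmf_kernel_bank`: a list of 16
#'   `mlvmf_kernel` objects named `K1` ... `K16`, each with fields `id`,
#'   `weights` (5x5 integer matrix), `round` (`"first"` or `"second"`) and
#'   `angle` (radians).
#' @examples
#' bank <- build_kernel_bank()
#' bank$K5
#' all(vapply(bank, function(k) sum(k$weights), 0) == 0)
#' @export
build_kernel_bank <- function() {
  offs <- direction_offsets()
  angles <- c(0, pi / 4, pi / 2, 3 * pi / 4,
              pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)
  bank <- vector("list", 16L)
  for (d in 1:8) {
    bank[[d]] <- kernel_from_offsets(paste0("K", d), offs[[d]],
                                     "first", angles[d])
    ring <- offs[[d]][pmax(abs(offs[[d]][, 1]), abs(offs[[d]][, 2])) == 2L, ,
                      drop = FALSE]
    bank[[d + 8L]] <- kernel_from_offsets(paste0("K", d + 8L), ring,
                                          "second", angles[d])
  }
  names(bank) <- vapply(bank, `[[`, "", "id")
  structure(bank, class = "mlvmf_kernel_bank")
}

#' @export
print.mlvmf_kernel_bank <- function(x, ...) {
  cat("<mlvmf_kernel_bank: 16 directional Laplacian kernels (5x5)>\n")
  cat("  round one:", paste(names(x)[1:8], collapse = " "), "\n")
  cat("  round two:", paste(names(x)[9:16], collapse = " "),
      "(direct-neighbor-blind)\n")
  invisible(x)
}

#' Subset a bank to one detection round
#' @param bank a [build_kernel_bank()] object.
#' @param round `"first"` (K1-K8) or `"second"` (K9-K16).
#' @return a list of 8 kernels in id order.
#' @export
round_kernels <- function(bank, round = c("first", "second")) {
  round <- match.arg(round)
  bank[vapply(bank, function(k) k$round == round, NA)]
}

#' Classic 3x3 discrete Laplacian stencils
#'
#' The two standard small approximations to the Laplacian operator, with
#' the same positive-center sign convention as the 5x5 bank. They are
#' provided for reference and comparison; the detector itself uses the 5x5
#' directional bank.
#'
#' @param variant `"four_neighbor"` (center +4, cross of -1) or
#'   `"eight_neighbor"` (center +8, ring of -1).
#' @return a 3x3 integer matrix summing to zero.
#' @export
reference_laplacian_3x3 <- function(variant = c("four_neighbor",
                                                "eight_neighbor")) {
  variant <- match.arg(variant)
  if (variant == "four_neighbor")
    matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3L, 3L, byrow = TRUE)
  else
    matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3L, 3L, byrow = TRUE)
}

#' Machine-readable kernel dump
#'
#' Writes the bank as JSON (one object per kernel: id, round, angle as a
#' multiple of pi/8, and the 5x5 weight rows) so transcribed weights can be
#' inspected and diffed.
#'
#' @param bank a [build_kernel_bank()] object.
#' @param path output path, or `NULL` to return the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
kernel_bank_json <- function(bank = build_kernel_bank(), path = NULL) {
  lst <- lapply(bank, function(k) list(
    id = k$id, round = k$round, angle_over_pi8 = round(k$angle / (pi / 8)),
    weights = apply(k$weights, 1, identity, simplify = FALSE)
  ))
  js <- jsonlite::toJSON(unname(lst), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Checksum of the kernel bank weights
#'
#' A 32-bit FNV-1a hash over the concatenated weight grids in id order,
#' embedded in reports for provenance (a restored image is only
#' reproducible given the exact kernel coefficients).
#'
#' @param bank a [build_kernel_bank()] object.
#' @return hex string.
#' @export
kernel_bank_checksum <- function(bank = build_kernel_bank()) {
  bytes <- utf8ToInt(paste(
    vapply(bank, function(k) paste(as.integer(k$weights), collapse = ","),
           ""), collapse = ";"))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double < 2^32
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply split in 16-bit halves to stay exact in doubles
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}
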