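# Independent brute-force references, written against the definitions only.
# They share no code with the package internals they check.

oracle_pad <- function(mat, k, border = "replicate") {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(0, n + 2 * k, m + 2 * k)
  for (i in seq_len(n + 2 * k)) {
    for (j in seq_len(m + 2 * k)) {
      r <- i - k; c_ <- j - k
      if (border == "replicate") {
        r <- min(max(r, 1), n); c_ <- min(max(c_, 1), m)
        out[i, j] <- mat[r, c_]
      } else if (r >= 1 && r <= n && c_ >= 1 && c_ <= m) {
        out[i, j] <- mat[r, c_]
      }
    }
  }
  out
}

# per-pixel quadruple-loop |convolution|
oracle_convolve_abs <- function(channel, weights, border = "replicate") {
  k <- (nrow(weights) - 1) / 2
  p <- oracle_pad(channel, k, border)
  n <- nrow(channel); m <- ncol(channel)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- 0
      for (u in seq_len(nrow(weights)))
        for (v in seq_len(ncol(weights)))
          s <- s + weights[u, v] * p[i + u - 1, j + v - 1]
      out[i, j] <- abs(s)
    }
  }
  out
}

# full chain: 24 responses -> min + argmin (id order ties) -> T + 0/255 rule
oracle_detect_chain <- function(image, kernels, threshold) {
  n <- dim(image)[1]; m <- dim(image)[2]
  resp <- vector("list", length(kernels))
  for (i in seq_along(kernels))
    resp[[i]] <- lapply(1:3, function(j)
      oracle_convolve_abs(image[, , j], kernels[[i]]$weights))
  M <- matrix(0, n, m); flag <- matrix(FALSE, n, m)
  for (x in seq_len(n)) {
    for (y in seq_len(m)) {
      best <- Inf; bj <- 1L
      for (i in seq_along(kernels)) {
        for (j in 1:3) {
          v <- resp[[i]][[j]][x, y]
          if (v < best) { best <- v; bj <- j }
        }
      }
      M[x, y] <- best
      flag[x, y] <- best > threshold && image[x, y, bj] %in% c(0, 255)
    }
  }
  list(M = M, flagged = flag)
}

oracle_vector_median <- function(window, norm = "L1") {
  k <- nrow(window)
  best <- Inf; sel <- 1L
  for (a in seq_len(k)) {
    s <- 0
    for (b in seq_len(k)) {
      s <- s + if (norm == "L1") sum(abs(window[a, ] - window[b, ]))
               else sqrt(sum((window[a, ] - window[b, ])^2))
    }
    if (s < best) { best <- s; sel <- a }
  }
  window[sel, ]
}

# per-pixel 3x3 vector median of a whole image, replicate borders
oracle_vmf_full <- function(image, norm = "L1") {
  n <- dim(image)[1]; m <- dim(image)[2]
  out <- image
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      win <- matrix(0, 9, 3); o <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          o <- o + 1
          r <- min(max(i + dr, 1), n); c_ <- min(max(j + dc, 1), m)
          win[o, ] <- image[r, c_, ]
        }
      }
      out[i, j, ] <- oracle_vector_median(win, norm)
    }
  }
  out
}

random_test_image <- function(n, m, gray = FALSE) {
  if (gray) {
    g <- matrix(sample(0:255, n * m, replace = TRUE), n, m)
    as_rgb_image(g)
  } else {
    as_rgb_image(array(sample(0:255, n * m * 3, replace = TRUE), c(n, m, 3)))
  }
}

rot90_image <- function(image) {
  n <- dim(image)[1]; m <- dim(image)[2]
  out <- array(0, c(m, n, 3))
  for (ch in 1:3) out[, , ch] <- t(image[, , ch])[m:1, ]
  as_rgb_image(out)
}

rot90_mat <- function(mat) t(mat)[ncol(mat):1, ]
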