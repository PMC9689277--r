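test_that("convolve_abs matches a naive quadruple-loop oracle exactly", {
  set.seed(21)
  bank <- build_kernel_bank()
  for (rep in 1:10) {
    ch <- matrix(sample(0:255, 81, TRUE), 9, 9)
    k <- bank[[sample(16, 1)]]
    for (border in c("replicate", "zero")) {
      expect_identical(convolve_abs(ch, k, border),
                       oracle_convolve_abs(ch, k$weights, border))
    }
  }
})

test_that("an isolated extreme pixel responds with |center weight| * 255", {
  z <- matrix(0, 9, 9); z[5, 5] <- 255
  for (k in build_kernel_bank())
    expect_equal(convolve_abs(z, k)[5, 5], k$weights[3, 3] * 255,
                 label = k$id)
})

test_that("variation tensor stacks 24 planes; identical channels give identical planes", {
  img <- random_test_image(10, 12, gray = TRUE)
  v <- variation_tensor(img, round = "first")
  expect_identical(dim(v), c(10L, 12L, 8L, 3L))
  expect_equal(prod(dim(v)[3:4]), 24)
  for (i in 1:8) {
    expect_identical(v[, , i, 1], v[, , i, 2])
    expect_identical(v[, , i, 1], v[, , i, 3])
  }
  flat <- as_rgb_image(array(77, c(8, 8, 3)))
  expect_true(all(variation_tensor(flat, round = "second") == 0))
})

test_that("min_variation takes the 24-way minimum with id-order tie-break", {
  img <- random_test_image(6, 6)
  v <- variation_tensor(img, round = "first")
  mv <- min_variation(v)
  for (x in 1:6) {
    for (y in 1:6) {
      expect_equal(mv$M[x, y], min(v[x, y, , ]))
      expect_equal(v[x, y, mv$argmin_kernel[x, y], mv$argmin_channel[x, y]],
                   mv$M[x, y])
    }
  }
  # all-equal tie at every pixel -> first kernel, red channel
  flat <- as_rgb_image(array(200, c(6, 6, 3)))
  mvf <- min_variation(variation_tensor(flat, round = "first"))
  expect_true(all(mvf$argmin_kernel == 1L))
  expect_true(all(mvf$argmin_channel == 1L))
  expect_true(all(mvf$M == 0))
})

test_that("detection needs both the threshold and the extreme-value test", {
  flat <- as_rgb_image(array(128, c(11, 11, 3)))
  mv <- min_variation(variation_tensor(flat, round = "first"))
  expect_false(any(detect_impulses(flat, mv, 75)$flagged))

  # isolated 255 impulse on 128: flagged
  imp <- flat; imp[6, 6, ] <- 255
  imp <- as_rgb_image(imp)
  mask <- detect_impulses(imp,
    min_variation(variation_tensor(imp, round = "first")), 75)
  expect_true(mask$flagged[6, 6])
  expect_equal(sum(mask$flagged), 1)

  # a 200-valued outlier on a 0 background exceeds T but fails the 0/255 rule
  z <- array(0, c(11, 11, 3)); z[6, 6, ] <- 200
  # ... except every background pixel IS 0; restrict to the outlier itself
  zi <- as_rgb_image(z)
  mvz <- min_variation(variation_tensor(zi, round = "first"))
  expect_gt(mvz$M[6, 6], 75)
  expect_false(detect_impulses(zi, mvz, 75)$flagged[6, 6])
})

test_that("full detector chain equals an independent brute-force reference", {
  set.seed(33)
  bank <- build_kernel_bank()
  sizes <- cbind(sample(6:16, 60, TRUE), sample(6:16, 60, TRUE))
  for (t in seq_len(nrow(sizes))) {
    img <- random_test_image(sizes[t, 1], sizes[t, 2])
    rd <- if (t %% 2 == 0) "first" else "second"
    ks <- round_kernels(bank, rd)
    got_mv <- min_variation(variation_tensor(img, bank, rd))
    got <- detect_impulses(img, got_mv, 75)
    want <- oracle_detect_chain(img, ks, 75)
    expect_identical(got_mv$M, want$M)
    expect_identical(got$flagged, want$flagged)
  }
})

test_that("detections rotate with the image (bank closure)", {
  set.seed(55)
  ph <- make_phantom("blocks", 24, 24)
  rec <- add_salt_pepper(ph, noise_spec(8, seed = 13))
  img <- rec$noisy
  for (rd in c("first", "second")) {
    mask <- detect_impulses(img,
      min_variation(variation_tensor(img, round = rd)), 75)$flagged
    rot <- rot90_image(img)
    mask_rot <- detect_impulses(rot,
      min_variation(variation_tensor(rot, round = rd)), 75)$flagged
    expect_identical(mask_rot, rot90_mat(mask))
  }
})

test_that("collision pairs: round-one vs round-two visibility matches the oracle", {
  # 2x1 4-connected pair of 255 impulses in a flat 60 background
  ph <- as_rgb_image(array(60, c(15, 15, 3)))
  rec <- plant_collision(ph, rbind(c(7, 7), c(7, 8)), 255)
  bank <- build_kernel_bank()
  o1 <- oracle_detect_chain(rec$noisy, round_kernels(bank, "first"), 75)
  got1 <- detect_impulses(rec$noisy,
    min_variation(variation_tensor(rec$noisy, bank, "first")), 75)
  expect_identical(got1$flagged, o1$flagged)
  # with these kernels at most one negative cell of any first-round kernel
  # falls on the partner impulse, so the pair is already seen in round one
  expect_true(all(o1$flagged[8, 8:9]))

  # a pixel whose whole 8-neighborhood is corrupted at the same value is
  # still seen by the direct-neighbor-blind bank
  blk <- as.matrix(expand.grid(6:8, 6:8))
  rec3 <- plant_collision(ph, blk, 255)
  got2 <- detect_impulses(rec3$noisy,
    min_variation(variation_tensor(rec3$noisy, bank, "second")), 75)
  expect_true(got2$flagged[8, 8])   # center of the 3x3 block
})
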