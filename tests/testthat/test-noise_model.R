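test_that("zero percentage leaves the image untouched; 100% salt saturates it", {
  ph <- make_phantom("gradient", 24, 24)
  rec0 <- add_salt_pepper(ph, noise_spec(0, seed = 5))
  expect_identical(rec0$noisy, ph)
  expect_false(any(rec0$truth_mask))

  rec1 <- add_salt_pepper(ph, noise_spec(100, salt_fraction = 1, seed = 5))
  expect_true(all(rec1$noisy == 255))
  expect_true(all(rec1$truth_mask))
})

test_that("corrupted-pixel count lands in the central 99.9% binomial band", {
  # independent bound: qbinom on Binomial(256*256, 0.1)
  lo <- qbinom(0.0005, 256 * 256, 0.1)
  hi <- qbinom(0.9995, 256 * 256, 0.1)
  rec <- add_salt_pepper(make_phantom("flat", 256, 256),
                         noise_spec(10, seed = 42))
  expect_gte(sum(rec$truth_mask), lo)
  expect_lte(sum(rec$truth_mask), hi)
})

test_that("masks are faithful and corrupted samples obey the 0/255 value law", {
  ph <- make_phantom("blocks", 40, 40)
  for (mode in c("monochrome", "channelwise")) {
    rec <- add_salt_pepper(ph, noise_spec(20, mode = mode, seed = 9))
    diff <- rec$noisy != ph
    expect_identical(array(diff, dim(diff)), unclass(rec$per_channel_mask))
    expect_identical(rec$truth_mask,
                     diff[, , 1] | diff[, , 2] | diff[, , 3])
    expect_true(all(rec$noisy[rec$per_channel_mask] %in% c(0, 255)))
    # untouched pixels byte-identical
    expect_true(all(rec$noisy[!rec$per_channel_mask] ==
                    ph[!rec$per_channel_mask]))
  }
})

test_that("monochrome mode corrupts whole pixels, channelwise individual samples", {
  ph <- make_phantom("flat", 48, 48)
  mono <- add_salt_pepper(ph, noise_spec(25, seed = 2, mode = "monochrome"))
  hit <- mono$per_channel_mask
  expect_identical(hit[, , 1], hit[, , 2])
  expect_identical(hit[, , 1], hit[, , 3])

  chan <- add_salt_pepper(ph, noise_spec(25, seed = 2, mode = "channelwise"))
  h <- chan$per_channel_mask
  expect_false(identical(h[, , 1], h[, , 2]))
})

test_that("identical spec + seed reproduce the corruption; the RNG state is restored", {
  ph <- make_phantom("chest_like", 32, 32, seed = 4)
  set.seed(123); before <- runif(1)
  set.seed(123)
  rec1 <- add_salt_pepper(ph, noise_spec(15, seed = 77))
  after <- runif(1)
  rec2 <- add_salt_pepper(ph, noise_spec(15, seed = 77))
  expect_identical(rec1, rec2)
  expect_identical(before, after)
})

test_that("noise_spec validates its ranges", {
  expect_error(noise_spec(-1), "percentage")
  expect_error(noise_spec(101), "percentage")
  expect_error(noise_spec(10, salt_fraction = 1.5), "salt_fraction")
})

test_that("plant_collision sets exactly the listed pixels in all channels", {
  ph <- make_phantom("flat", 20, 20)
  expect_identical(plant_collision(ph, matrix(numeric(0), 0, 2), 255)$noisy, ph)

  pair <- rbind(c(5, 5), c(5, 6))                 # 4-connected, 0-based coords
  rec <- plant_collision(ph, pair, 255)
  expect_equal(sum(rec$truth_mask), 2)
  expect_true(rec$truth_mask[6, 6] && rec$truth_mask[6, 7])
  expect_true(all(rec$noisy[6, 6, ] == 255) && all(rec$noisy[6, 7, ] == 255))

  blk <- as.matrix(expand.grid(8:9, 11:12))       # 2x2 block
  rec2 <- plant_collision(ph, blk, 0)
  expect_true(all(rec2$noisy[9:10, 12:13, ] == 0))
  expect_equal(sum(rec2$truth_mask), 4)

  expect_error(plant_collision(ph, rbind(c(25, 3)), 0), "outside")
  expect_error(plant_collision(ph, rbind(c(1, 1)), 128), "0 or 255")
})

test_that("phantoms are 8-bit, in [1,254], piecewise-smooth and deterministic", {
  for (kind in c("flat", "gradient", "blocks", "chest_like")) {
    ph <- make_phantom(kind, 32, 48, seed = 6)
    expect_identical(dim(ph), c(32L, 48L, 3L))
    expect_gte(min(ph), 1); expect_lte(max(ph), 254)
    expect_true(is_gray(ph))
    expect_identical(ph, make_phantom(kind, 32, 48, seed = 6))
  }
  expect_true(all(make_phantom("flat", 16, 16) == 128))
  # blocks: at least 4 distinct constant tiles with step edges >= 60
  blocks <- make_phantom("blocks", 64, 64)[, , 1]
  expect_gte(length(unique(as.vector(blocks))), 4)
  hsteps <- abs(diff(t(blocks))); vsteps <- abs(diff(blocks))
  steps <- c(hsteps[hsteps > 0], vsteps[vsteps > 0])
  expect_gte(min(steps), 60)
  expect_error(make_phantom("flat", 8, 32), ">= 16")
  expect_error(make_phantom("spiral", 32, 32))
})
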