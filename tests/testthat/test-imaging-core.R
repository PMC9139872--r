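test_that("images round-trip losslessly through PNG and rescale from other depths", {
  px <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
  img <- rgb_image(px)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_identical(unclass(load_image(path)), unclass(img))

  # 16-bit TIFF full scale maps to 255
  t16 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(array(1, dim = c(2, 2, 3)), t16, bits.per.sample = 16L)
  expect_true(all(load_image(t16) == 255L))

  # grayscale replicates across channels
  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(128 / 255, 2, 2), gray)
  g <- load_image(gray)
  expect_true(all(g == 128L))
  expect_equal(dim(g), c(2L, 2L, 3L))

  # alpha channel is dropped
  rgba <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(c(rep(0.5, 12), rep(1, 4)), dim = c(2, 2, 4)), rgba)
  expect_equal(dim(load_image(rgba)), c(2L, 2L, 3L))

  expect_error(load_image("does-not-exist.png"), "not found")
  bad <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", bad)
  expect_error(load_image(bad), "unsupported")
})

test_that("rgb_image rejects invalid pixel containers", {
  expect_error(rgb_image(matrix(0, 2, 2)), "H x W x 3")
  expect_error(rgb_image(array(-1, dim = c(2, 2, 3))), "0, 255")
  expect_error(rgb_image(array(256, dim = c(2, 2, 3))), "0, 255")
})

test_that("channel shielding keeps only the designated channel and is idempotent", {
  img <- uniform_image(200, 150, 100)
  red <- shield_channel(img, "red")
  expect_true(all(red[, , 1] == 200 & red[, , 2] == 0 & red[, , 3] == 0))

  # a pure-green marker disappears behind a red shield
  green_marker <- uniform_image(0, 255, 0)
  expect_true(all(shield_channel(green_marker, "red") == 0))
  # own-color passes through
  blue <- uniform_image(0, 0, 255)
  expect_identical(unclass(shield_channel(blue, "blue")), unclass(blue))

  for (ch in c("red", "green", "blue")) {
    img <- random_image(8, 8, seed = 42)
    once <- shield_channel(img, ch)
    expect_identical(unclass(shield_channel(once, ch)), unclass(once))
  }
})

test_that("low-red suppression unifies sub-threshold pixels with the background", {
  img <- split_red_image(30, 200)
  out <- suppress_low_red(img, 50)
  left <- out$image[, 1:2, ]
  expect_true(all(left == 0))
  expect_identical(out$image[, 3:4, ], unclass(img)[, 3:4, ])
  expect_identical(out$mask, unclass(img)[, , 1] >= 50)

  # threshold 0 keeps everything; 256 removes everything
  img2 <- random_image(6, 6, seed = 7)
  expect_true(all(suppress_low_red(img2, 0)$mask))
  expect_false(any(suppress_low_red(img2, 256)$mask))
})

test_that("suppression mask matches generated ground truth at a separating threshold", {
  fx <- make_gastric_image(background_rgb = c(80, 145, 150), lesion_red = 220,
                           noise_sd = 0, area_fraction_target = 0.1,
                           size = c(64, 64), seed = 3)
  out <- suppress_low_red(fx$image, 150)
  expect_identical(out$mask, fx$mask)
})

test_that("brightness levels act as inverse scale factors with clipping", {
  img <- random_image(8, 8, seed = 11)
  expect_identical(unclass(adjust_brightness(img, 100)), unclass(img))
  expect_true(all(adjust_brightness(uniform_image(100), 200) == 50))
  expect_true(all(adjust_brightness(uniform_image(200), 50) == 255))
  expect_error(adjust_brightness(img, 0), "positive")
  expect_error(adjust_brightness(img, -50), "positive")

  # 50 then 200 is the identity wherever level-50 did not clip
  img2 <- uniform_image(90, 17, 120)
  expect_identical(unclass(adjust_brightness(adjust_brightness(img2, 50), 200)),
                   unclass(img2))
})

test_that("card correction is the identity on matched cards and exact on affine casts", {
  card <- card_from_matrix(matrix(c(50, 100, 200,  60, 120, 180,  70, 140, 210),
                                  ncol = 3, byrow = FALSE))
  img <- random_image(8, 8, seed = 5)
  expect_identical(unclass(correct_with_card(img, card, card)), unclass(img))

  # measured at half the reference -> gain 2, offset 0
  ref <- card_from_matrix(matrix(c(100, 200, 50, 150, 80, 160), ncol = 3))
  meas <- card_from_matrix(as.matrix(ref[, c("red", "green", "blue")]) / 2)
  px <- uniform_image(100, 50, 25)
  corrected <- correct_with_card(px, meas, ref)
  expect_equal(corrected[1, 1, ], c(200L, 100L, 50L))
})

test_that("card correction recovers random per-channel gain and offset", {
  # oracle: closed-form two-parameter least squares per channel
  ols2 <- function(x, y) {
    g <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(gain = g, offset = mean(y) - g * mean(x))
  }
  withr::with_seed(99, {
    for (rep in 1:5) {
      true_gain <- runif(3, 0.5, 2)
      true_off <- runif(3, -20, 20)
      # reference range chosen so the implied measured card stays in [0, 255]
      ref_vals <- matrix(runif(24, 45, 110), ncol = 3)
      # build measured card so that gain * measured + offset = reference
      meas_vals <- sweep(sweep(ref_vals, 2, true_off, "-"), 2, true_gain, "/")
      fit <- card_correction_fit(card_from_matrix(meas_vals),
                                 card_from_matrix(ref_vals))
      for (k in 1:3) {
        oracle <- ols2(meas_vals[, k], ref_vals[, k])
        expect_equal(fit$gain[k], unname(oracle["gain"]), tolerance = 1e-9)
        expect_equal(fit$offset[k], unname(oracle["offset"]), tolerance = 1e-9)
        expect_equal(fit$gain[k], true_gain[k], tolerance = 1e-6)
        expect_equal(fit$offset[k], true_off[k], tolerance = 1e-6)
      }
    }
  })
  # degenerate: identical patches cannot be fitted
  flat <- card_from_matrix(matrix(100, nrow = 3, ncol = 3))
  ref <- card_from_matrix(matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), ncol = 3))
  expect_error(correct_with_card(uniform_image(10), flat, ref), "degenerate")
})

test_that("card patches are measured from layout boxes and JSON sidecars parse", {
  px <- array(0, dim = c(10, 10, 3))
  px[1:5, 1:5, 1] <- 200; px[1:5, 1:5, 2] <- 100; px[1:5, 1:5, 3] <- 50
  px[6:10, 6:10, 1] <- 20; px[6:10, 6:10, 2] <- 40; px[6:10, 6:10, 3] <- 60
  img <- rgb_image(px)
  layout <- data.frame(x = c(0, 5), y = c(0, 5), w = c(5, 5), h = c(5, 5))
  meas <- measure_card_patches(img, layout)
  expect_equal(meas$red, c(200, 20))
  expect_equal(meas$blue, c(50, 60))

  sidecar <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(patches = data.frame(
    x = c(0, 5), y = c(0, 5), w = 5, h = 5,
    reference = I(list(c(255, 255, 255), c(0, 0, 0)))
  )), auto_unbox = TRUE), sidecar)
  lay <- read_card_layout(sidecar)
  expect_equal(lay$red, c(255, 0))
  expect_equal(lay$x, c(0, 5))
})

test_that("all imaging outputs remain valid 8-bit images", {
  img <- random_image(10, 10, seed = 2)
  outs <- list(
    shield_channel(img, "green"),
    suppress_low_red(img, 128)$image,
    adjust_brightness(img, 50),
    adjust_brightness(img, 200)
  )
  for (o in outs) {
    expect_s3_class(o, "rgb_image")
    expect_true(min(o) >= 0 && max(o) <= 255)
  }
})
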