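test_that("compute_mse matches closed forms and the naive-loop oracle", {
  a <- uimg(4, 4, c(10, 20, 30))
  expect_identical(compute_mse(a, a), 0)
  b <- rgb_image(unclass(a) + 1L)
  expect_equal(compute_mse(a, b), 1.0)
  r1 <- rand_img(8, 8, seed = 21); r2 <- rand_img(8, 8, seed = 22)
  expect_equal(compute_mse(r1, r2), naive_mse(r1, r2), tolerance = 1e-12)
  expect_equal(compute_mse(r1, r2), compute_mse(r2, r1))
  expect_error(compute_mse(r1, rand_img(8, 9, 1)), "dimension mismatch")
})

test_that("compute_psnr follows the formula, with an Inf sentinel at MSE 0", {
  a <- uimg(3, 3, c(5, 5, 5))
  expect_identical(compute_psnr(a, a), Inf)
  black <- uimg(3, 3, c(0, 0, 0)); white <- uimg(3, 3, c(255, 255, 255))
  expect_equal(compute_psnr(black, white), 0)      # MSE = 255^2
  r1 <- rand_img(8, 8, seed = 31); r2 <- rand_img(8, 8, seed = 32)
  expect_equal(compute_psnr(r1, r2),
               10 * log10(255^2 / naive_mse(r1, r2)), tolerance = 1e-9)
})

test_that("window selection implements the published <= 20 dB rule", {
  expect_identical(select_filter_window(18), 5L)
  expect_identical(select_filter_window(35), 3L)
  expect_identical(select_filter_window(20), 5L)   # boundary is inclusive
  expect_identical(select_filter_window(Inf), 3L)
  expect_error(select_filter_window(-1), "non-negative")
})

test_that("median filter: constants, impulse removal, and the sort oracle", {
  const <- uimg(9, 9, c(70, 80, 90))
  expect_identical(unclass(median_filter(const, 3)), unclass(const))
  salt <- unclass(uimg(9, 9, c(0, 0, 0)))
  salt[5, 5, ] <- 255L
  expect_true(all(median_filter(rgb_image(salt), 3) == 0L))
  noisy <- rand_img(16, 16, seed = 41)
  for (side in c(3L, 5L))
    expect_identical(unclass(median_filter(noisy, side)),
                     unclass(naive_median_filter(noisy, side)))
  expect_error(median_filter(noisy, 4), "odd")
})

test_that("average brightness: black, white, and the naive oracle", {
  expect_equal(average_brightness(uimg(2, 2, c(0, 0, 0))), 0)
  expect_equal(average_brightness(uimg(2, 2, c(255, 255, 255))), 255)
  r <- rand_img(8, 8, seed = 51)
  expect_equal(average_brightness(r), naive_mean_luma(r), tolerance = 1e-9)
})

test_that("alpha selection reproduces the published step table", {
  expect_identical(select_alpha(5), 20L)
  expect_identical(select_alpha(100), 8L)
  expect_identical(select_alpha(250), 4L)
  # published boundaries are upper-inclusive
  expect_identical(select_alpha(10), 20L)
  expect_identical(select_alpha(40), 12L)
  expect_identical(select_alpha(150), 8L)
  expect_identical(select_alpha(200), 6L)
  expect_error(select_alpha(-0.1), "\\[0, 255\\]")
  expect_error(select_alpha(255.1), "\\[0, 255\\]")
  # non-increasing in y
  ys <- seq(0, 255, by = 0.5)
  expect_true(all(diff(vapply(ys, select_alpha, integer(1))) <= 0))
})

test_that("apply_gain saturates with half-up rounding", {
  img <- rand_img(6, 6, seed = 61)
  expect_identical(unclass(apply_gain(img, 1)), unclass(img))
  expect_true(all(apply_gain(uimg(2, 2, c(128, 128, 128)), 4) == 255L))
  expect_true(all(apply_gain(uimg(2, 2, c(10, 10, 10)), 8) == 80L))
  expect_true(all(apply_gain(uimg(2, 2, c(7, 7, 7)), 1.5) == 11L))  # 10.5 -> 11
  expect_error(apply_gain(img, 0), "positive")
})

test_that("preprocess runs the literal chain and fills provenance", {
  const <- uimg(16, 16, c(30, 30, 30))   # luma 30 -> alpha 12 -> saturates
  pre <- preprocess(const)
  expect_identical(pre$provenance$probe_psnr_db, Inf)
  expect_identical(pre$provenance$selected_window, 3L)
  expect_identical(pre$provenance$selected_alpha, 12L)
  expect_true(all(pre$image == pmin(30L * 12L, 255L)))
  expect_false(any(vapply(pre$provenance$stage_checksums, is.null, logical(1))))

  # heavy impulse noise drives the probe PSNR below 20 dB -> 5x5 window
  base <- uimg(48, 48, c(128, 128, 128))
  noisy <- add_impulse_noise(base, 0.2, seed = 9)
  expect_lte(compute_psnr(median_filter(noisy, 3), noisy), 20)
  pre2 <- preprocess(noisy)
  expect_identical(pre2$provenance$selected_window, 5L)

  # stage checksums match an independently recomputed chain
  II <- median_filter(noisy, 3)
  III <- median_filter(II, pre2$provenance$selected_window)
  IIII <- apply_gain(III, pre2$provenance$selected_alpha)
  expect_identical(pre2$provenance$stage_checksums$II, digest::digest(unclass(II)))
  expect_identical(pre2$provenance$stage_checksums$III, digest::digest(unclass(III)))
  expect_identical(pre2$provenance$stage_checksums$IIII, digest::digest(unclass(IIII)))
  expect_identical(unclass(pre2$image), unclass(IIII))
})

test_that("median filtering improves PSNR against the clean image", {
  for (s in 1:3) {
    fx <- make_ihc_image(fixture_spec(height = 96, width = 96, seed = 70 + s,
                                      positive_fraction = 0.2,
                                      nucleus_radius_px = 6,
                                      nucleus_radius_spread = 1,
                                      impulse_noise_density = 0.05))
    clean <- fx$truth$clean_image
    filtered <- median_filter(fx$image, 3)
    expect_gt(compute_psnr(filtered, clean), compute_psnr(fx$image, clean))
  }
})
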