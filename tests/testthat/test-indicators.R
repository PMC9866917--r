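seg_stub <- function(sp, sw, h = 10, w = 10, mask = NULL) {
  if (is.null(mask)) { mask <- matrix(FALSE, h, w); if (sp > 0) mask[seq_len(sp)] <- TRUE }
  structure(list(foreground_mask = mask, labels = matrix(0L, h, w),
                 positive_area_sp = as.integer(sp), window_area_sw = as.integer(sw),
                 n_objects = 0L, params_used = list()),
            class = "segmentation_result")
}

test_that("relative area is exact Sp/Sw", {
  expect_equal(relative_area(seg_stub(100, 100))$delta_s, 1.0)
  expect_equal(relative_area(seg_stub(0, 100))$delta_s, 0.0)
  expect_equal(relative_area(seg_stub(2500, 10000, 100, 100))$delta_s, 0.25)
  expect_error(relative_area(seg_stub(0, 0)), "positive")
})

test_that("masked mean brightness: uniform, consistency, naive oracle", {
  img <- uimg(6, 6, c(20, 20, 20))
  mask <- matrix(FALSE, 6, 6); mask[2:3, 2:3] <- TRUE
  expect_equal(masked_mean_brightness(img, mask), 20)
  r <- rand_img(7, 7, seed = 81)
  expect_equal(masked_mean_brightness(r, matrix(TRUE, 7, 7)),
               average_brightness(r))
  set.seed(82); m2 <- matrix(runif(49) > 0.5, 7, 7)
  acc <- 0; n <- 0
  for (i in 1:7) for (j in 1:7) if (m2[i, j]) {
    acc <- acc + 0.299 * r[i, j, 1] + 0.587 * r[i, j, 2] + 0.114 * r[i, j, 3]
    n <- n + 1
  }
  expect_equal(masked_mean_brightness(r, m2), acc / n, tolerance = 1e-9)
  expect_error(masked_mean_brightness(r, matrix(FALSE, 7, 7)),
               "no positive cells")
})

test_that("intensity coefficient reproduces the published bins", {
  expect_identical(intensity_coefficient(10)$ki, 1L)
  expect_identical(intensity_coefficient(20)$ki, 2L)
  expect_identical(intensity_coefficient(40)$ki, 3L)
  # bin edges and the (15, 16) gap, closed half-open
  expect_identical(intensity_coefficient(15)$ki, 1L)
  expect_identical(intensity_coefficient(15.5)$ki, 2L)
  expect_identical(intensity_coefficient(16)$ki, 2L)
  expect_identical(intensity_coefficient(30)$ki, 2L)
  expect_identical(intensity_coefficient(30.001)$ki, 3L)
  expect_error(intensity_coefficient(-1), "\\[0, 255\\]")
  expect_error(intensity_coefficient(256), "\\[0, 255\\]")
  # monotone non-decreasing and total on [0, 255]
  ys <- seq(0, 255, by = 0.25)
  kis <- vapply(ys, function(y) intensity_coefficient(y)$ki, integer(1))
  expect_true(all(diff(kis) >= 0))
})

test_that("indicator_set construction validates completeness and ranges", {
  expect_error(indicator_set(c(ER = 0.5, PR = 0.1)), "missing biomarker")
  expect_error(ind_from(1.5, 0, 0, 0), "\\[0, 1\\]")
  expect_error(ind_from(0.5, 0.5, 0.5, 0.5, er_ki = 5), "1, 2 or 3")
  ind <- ind_from(0.7, 0.3, 0.05, 0.1, er_ki = 3)
  expect_identical(ind$ER$ki, 3L)
  expect_true(is.na(ind$PR$ki))
  expect_true(ind$HER2$sigma_s == 0.05)
})

test_that("compute_indicator_set: blanks, completeness, determinism", {
  blank <- uimg(48, 48, c(255, 255, 255))
  stack <- list(er = blank, pr = blank, her2 = blank, ki67 = blank)
  ind <- compute_indicator_set(stack)
  for (bm in BIOMARKERS) {
    expect_equal(ind[[bm]]$sigma_s, 0)
    expect_true(ind[[bm]]$no_positive_cells)
    expect_true(is.na(ind[[bm]]$ki))
    expect_s3_class(ind[[bm]]$provenance, "provenance_record")
  }
  expect_error(compute_indicator_set(list(ER = blank, PR = blank)),
               "missing biomarker")
  ind2 <- compute_indicator_set(stack)
  ind$ER$provenance <- NULL; ind2$ER$provenance <- NULL  # env-free compare
  expect_identical(unclass(ind)[c("ER", "PR")], unclass(ind2)[c("ER", "PR")])
})

test_that("a Luminal-A-parameterized case yields in-tolerance indicators", {
  cs <- make_subtype_case("LuminalA", seed = 5)
  ind <- compute_indicator_set(cs$stack, ihc_config(cs$config))
  expect_lt(abs(ind$ER$sigma_s - cs$truth$ER$true_delta_s), 0.05)
  expect_lt(abs(ind$PR$sigma_s - cs$truth$PR$true_delta_s), 0.05)
  expect_identical(ind$ER$ki, 3L)
  expect_lt(abs(ind$ER$mean_brightness - cs$truth$ER$true_mean_luma), 10)
})
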