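test_that("rgb_image enforces its invariants", {
  expect_s3_class(uimg(2, 2, c(255, 255, 255)), "rgb_image")
  expect_error(rgb_image(array(0, c(2, 2, 4))), "3 array")
  expect_error(rgb_image(array(-1, c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(rgb_image(array(256, c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(rgb_image(array(0.5, c(2, 2, 3))), "integers")
  m <- rgb_image(matrix(7, 3, 4))
  expect_equal(dim(m), c(3L, 4L, 3L))
  expect_true(all(m == 7L))
})

test_that("biomarker and grade aliases normalize, unknowns error", {
  expect_equal(biomarker("estrogen"), "ER")
  expect_equal(biomarker("Ki-67"), "KI67")
  expect_equal(biomarker("HER2/neu"), "HER2")
  expect_equal(biomarker("pr"), "PR")
  expect_error(biomarker("cd34"), "unknown biomarker")
  expect_equal(grade("g2"), "G2")
  expect_equal(grade(3), "G3")
  expect_null(grade(NULL))
  expect_error(grade("G4"), "unknown grade")
})

test_that("PNG read/write round-trips bit-exactly, channels stay RGB", {
  withr::local_dir(withr::local_tempdir())
  white <- uimg(2, 2, c(255, 255, 255))
  write_image(white, "w.png")
  expect_true(all(read_image("w.png") == 255L))
  # asymmetric colors pin the channel order
  asym <- uimg(3, 5, c(200, 90, 10))
  write_image(asym, "a.png")
  back <- read_image("a.png")
  expect_identical(unclass(back), unclass(asym))
  fx <- make_ihc_image(fixture_spec(height = 48, width = 48, seed = 3,
                                    positive_fraction = 0.1,
                                    nucleus_radius_px = 5,
                                    nucleus_radius_spread = 1,
                                    negative_count = 2L))
  write_image(fx$image, "fx.png")
  expect_identical(unclass(read_image("fx.png")), unclass(fx$image))
})

test_that("uncompressed TIFF round-trips bit-exactly and rejects 16-bit", {
  withr::local_dir(withr::local_tempdir())
  img <- rand_img(9, 7, seed = 11)
  write_image(img, "x.tiff")
  expect_identical(unclass(read_image("x.tiff")), unclass(img))
  write_16bit_gray_tiff("deep.tiff")
  expect_error(read_image("deep.tiff"), "unsupported bit depth")
})

test_that("16-bit PNG and unreadable paths give explicit errors", {
  withr::local_dir(withr::local_tempdir())
  write_16bit_gray_png("deep.png")
  expect_error(read_image("deep.png"), "unsupported bit depth")
  expect_error(read_image("absent.png"), "no such file")
  writeBin(as.raw(1:10), "junk.png")
  expect_error(read_image("junk.png"), "corrupt|non-PNG")
})

test_that("grayscale PNG is replicated to 3 channels; JPEG warns", {
  withr::local_dir(withr::local_tempdir())
  png::writePNG(matrix(c(0, 1, 0.5, 0.25), 2, 2), "gray.png")
  img <- read_image("gray.png")
  expect_equal(dim(img)[3], 3L)
  expect_identical(img[, , 1], img[, , 3])
  jpeg::writeJPEG(array(0.5, c(4, 4, 3)), "x.jpg", quality = 1)
  expect_warning(img2 <- read_image("x.jpg"), "lossy")
  expect_s3_class(img2, "rgb_image")
})

test_that("mask write/read round-trips for constant and random masks", {
  withr::local_dir(withr::local_tempdir())
  all_fg <- matrix(TRUE, 4, 6)
  write_mask(all_fg, "fg.png")
  expect_true(all(read_mask("fg.png")))
  expect_true(all(png::readPNG("fg.png") == 1))
  write_mask(!all_fg, "bg.png")
  expect_false(any(read_mask("bg.png")))
  set.seed(5)
  rnd <- matrix(runif(35) > 0.5, 5, 7)
  write_mask(rnd, "r.png")
  expect_identical(read_mask("r.png"), rnd)
})

test_that("provenance record validates fields and serializes", {
  withr::local_dir(withr::local_tempdir())
  cks <- c(I = "a", II = "b", III = "c", IIII = "d")
  p <- provenance_record(Inf, 3L, 128, 8L, cks)
  expect_s3_class(p, "provenance_record")
  expect_error(provenance_record(20, 7L, 128, 8L, cks), "3 or 5")
  expect_error(provenance_record(20, 3L, 128, 5L, cks), "4, 6, 8, 12, 20")
  write_provenance(p, "prov.json")
  back <- jsonlite::read_json("prov.json")
  expect_equal(back$selected_window, 3L)
  expect_equal(back$probe_psnr_db, "Inf")
})
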