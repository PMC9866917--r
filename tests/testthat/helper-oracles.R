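# Independent brute-force oracles and tiny image builders. The oracles are
# deliberately naive (explicit loops) so they share no code path with the
# implementation they check.

uimg <- function(h, w, rgb) {
  arr <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- as.integer(rgb[ch])
  rgb_image(arr)
}

rand_img <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

naive_mse <- function(a, b) {
  acc <- 0; n <- 0
  for (i in seq_len(dim(a)[1]))
    for (j in seq_len(dim(a)[2]))
      for (ch in 1:3) {
        acc <- acc + (as.numeric(a[i, j, ch]) - as.numeric(b[i, j, ch]))^2
        n <- n + 1
      }
  acc / n
}

naive_mean_luma <- function(img) {
  acc <- 0
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(h))
    for (j in seq_len(w))
      acc <- acc + 0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3]
  acc / (h * w)
}

# half-sample symmetric reflection for 1-based indices
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

naive_median_filter <- function(img, side) {
  h <- dim(img)[1]; w <- dim(img)[2]; r <- side %/% 2
  out <- unclass(img)
  for (ch in 1:3)
    for (i in seq_len(h))
      for (j in seq_len(w)) {
        vals <- integer(0)
        for (di in -r:r)
          for (dj in -r:r)
            vals <- c(vals, img[reflect1(i + di, h), reflect1(j + dj, w), ch])
        out[i, j, ch] <- sort(vals)[(length(vals) + 1) %/% 2]
      }
  rgb_image(out)
}

# hard-edged disk test image: disk pixels at `fg` gray on `bg` gray
disk_image <- function(h, w, centers, r, fg = 80, bg = 245) {
  img <- array(bg, dim = c(h, w, 3))
  mask <- matrix(FALSE, h, w)
  for (cc in centers)
    for (i in seq_len(h))
      for (j in seq_len(w))
        if ((i - cc[1])^2 + (j - cc[2])^2 <= r^2) mask[i, j] <- TRUE
  for (ch in 1:3) { sl <- img[, , ch]; sl[mask] <- fg; img[, , ch] <- sl }
  list(img = rgb_image(img), mask = mask)
}

# indicator sets for rule tests
ind_from <- function(er_s, pr_s, her2_s, ki67_s,
                     er_ki = NA, her2_ki = NA, ki67_ki = NA, pr_ki = NA) {
  indicator_set(sigma_s = c(ER = er_s, PR = pr_s, HER2 = her2_s, KI67 = ki67_s),
                ki = c(ER = er_ki, PR = pr_ki, HER2 = her2_ki, KI67 = ki67_ki))
}

random_indicator_set <- function() {
  ind_from(runif(1), runif(1), runif(1), runif(1),
           er_ki = sample(1:3, 1), her2_ki = sample(1:3, 1),
           ki67_ki = sample(1:3, 1), pr_ki = sample(1:3, 1))
}

# minimal crafted 16-bit fixtures for bit-depth contract tests
write_16bit_gray_tiff <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(10L, con, size = 4L, endian = "little")   # IFD offset
  writeBin(c(0L, 0L), con, size = 1L)                # one 16-bit pixel
  wr <- function(tag, type, count, value) {
    writeBin(tag, con, size = 2L, endian = "little")
    writeBin(type, con, size = 2L, endian = "little")
    writeBin(count, con, size = 4L, endian = "little")
    if (type == 3L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  writeBin(7L, con, size = 2L, endian = "little")    # entry count
  wr(256L, 4L, 1L, 1L); wr(257L, 4L, 1L, 1L)
  wr(258L, 3L, 1L, 16L)                              # BitsPerSample = 16
  wr(259L, 3L, 1L, 1L); wr(273L, 4L, 1L, 8L)
  wr(277L, 3L, 1L, 1L); wr(279L, 4L, 1L, 2L)
  writeBin(0L, con, size = 4L, endian = "little")
  path
}

write_16bit_gray_png <- function(path) {
  # signature + IHDR declaring bit depth 16; the reader must reject on the
  # header alone, so no IDAT is needed
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  ihdr_data <- c(int32be(1L), int32be(1L), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  chunk <- c(int32be(length(ihdr_data)), charToRaw("IHDR"), ihdr_data,
             int32be(0L))  # CRC unchecked before the depth test
  writeBin(c(sig, chunk), path)
  path
}

int32be <- function(x) {
  as.raw(c(bitwAnd(bitwShiftR(x, 24), 255L), bitwAnd(bitwShiftR(x, 16), 255L),
           bitwAnd(bitwShiftR(x, 8), 255L), bitwAnd(x, 255L)))
}
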