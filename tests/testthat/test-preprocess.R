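test_that("tic_normalize rescales to the target TIC", {
  s <- mass_spectrum(c(100, 200), c(3, 1), "positive", centroided = TRUE)
  n <- tic_normalize(s, target = 1)
  expect_equal(sum(n$intensity), 1)
  expect_equal(n$intensity, c(0.75, 0.25))
  expect_equal(n$mz, s$mz)
  z <- mass_spectrum(c(100), c(0), "positive", centroided = TRUE)
  expect_error(tic_normalize(z), "all-zero")
})

test_that("tic_normalize_section flags all-zero pixels as missing", {
  spectra <- list(
    mass_spectrum(100, 4, "positive", centroided = TRUE),
    mass_spectrum(numeric(0), numeric(0), "positive", centroided = TRUE),
    mass_spectrum(100, 2, "positive", centroided = TRUE),
    mass_spectrum(100, 8, "positive", centroided = TRUE))
  sec <- section_dataset(spectra, 2, 2, 120)
  out <- tic_normalize_section(sec)
  expect_true(out$missing[1, 2])   # pixel (0, 1) row-major
  expect_false(out$missing[1, 1])
  expect_equal(sum(get_pixel(out, 1, 1)$intensity), 1)
})

test_that("pick_peaks centroids planted Gaussians to the grid oracle", {
  mus <- c(400.342, 428.373)
  prof <- gaussian_profile(mus, heights = c(100, 60), sigma = 0.01,
                           from = 399, to = 430)
  pk <- pick_peaks(prof, snr = 3, window = 0.05)
  expect_length(pk$mz, 2)
  oracle <- vapply(mus, centroid_oracle, numeric(1), sigma = 0.01)
  expect_lt(max(abs(pk$mz - oracle)), 0.005)
  expect_lt(max(abs(pk$mz - mus)), 0.005)
  # recall 1.0, centroid error < half the sampling step at high SNR
  expect_lt(max(abs(pk$mz - mus)), 0.002 / 2)
})

test_that("pick_peaks drops peaks below the SNR threshold", {
  set.seed(4)
  grid <- seq(100, 110, by = 0.01)
  noise_level <- 1
  y <- abs(rnorm(length(grid), sd = noise_level))
  noise <- 1.4826 * mad(y, constant = 1)
  # a peak at exactly 2 x noise with snr = 3 must be omitted
  y[501] <- 2 * noise
  prof <- mass_spectrum(grid, y, "positive", centroided = FALSE)
  pk <- pick_peaks(prof, snr = 3, window = 0.05)
  expect_false(any(abs(pk$mz - grid[501]) < 0.02))
  # raised to 10 x noise it must be found
  y[501] <- 10 * noise
  pk2 <- pick_peaks(mass_spectrum(grid, y, "positive", centroided = FALSE),
                    snr = 3)
  expect_true(any(abs(pk2$mz - grid[501]) < 0.02))
})

test_that("pick_peaks passes centroided spectra through and keeps plateau lows", {
  s <- mass_spectrum(c(100, 200), c(1, 2), "positive", centroided = TRUE)
  expect_identical(pick_peaks(s), s)
  # plateau: equal maxima -> the lower-m/z sample is kept
  grid <- seq(100, 101, by = 0.01)
  y <- rep(0.01, length(grid))
  y[50:51] <- 10
  pk <- pick_peaks(mass_spectrum(grid, y, "positive", centroided = FALSE),
                   snr = 3, window = 0.011)
  expect_length(pk$mz, 1)
  expect_equal(pk$mz[1], grid[50])
})

test_that("filter_mass_range keeps the closed interval", {
  s <- mass_spectrum(c(49.999, 50, 700, 1200, 1200.01), rep(1, 5),
                     "positive", centroided = TRUE)
  f <- filter_mass_range(s, 50, 1200)
  expect_equal(f$mz, c(50, 700, 1200))
  expect_error(filter_mass_range(s, 100, 100))
})

test_that("bin_peaks merges jittered channels and splits distant ones", {
  mk <- function(mzs, ints) {
    mass_spectrum(mzs, ints, "positive", centroided = TRUE)
  }
  # two pixels with the same channel jittered by ~5 ppm, plus a channel
  # 500 ppm away that must stay separate
  s1 <- section_dataset(list(mk(c(400.3421, 400.5423), c(10, 1)),
                             mk(400.3441, 5)), 1, 2, 120, section_index = 0)
  s2 <- section_dataset(list(mk(400.3401, 2),
                             mk(c(400.3421, 400.5421), c(8, 3))),
                        1, 2, 120, section_index = 1)
  dm <- bin_peaks(list(s1, s2), tolerance_ppm = 60)
  expect_s3_class(dm, "data_matrix")
  expect_equal(ncol(dm$matrix), 2)
  expect_equal(nrow(dm$matrix), 4)
  # bin centres are intensity-weighted means
  w <- c(10, 5, 2, 8); m <- c(400.3421, 400.3441, 400.3401, 400.3421)
  expect_equal(dm$bin_centers[1], sum(w * m) / sum(w), tolerance = 1e-9)
  # pixel_map is 0-based (section, row, col), row-major per section
  expect_equal(dm$pixel_map$section, c(0, 0, 1, 1))
  expect_equal(dm$pixel_map$col, c(0, 1, 0, 1))
  # intensities land in the right rows
  expect_equal(dm$matrix[, 1], c(10, 5, 2, 8))
  expect_equal(dm$matrix[, 2], c(1, 0, 0, 3))
})

test_that("bin_peaks splits clusters wider than the tolerance at largest gap", {
  # chain of centroids 15 ppm apart: every gap is below a 20 ppm
  # tolerance so single linkage joins them all, but the cluster is 45 ppm
  # wide and must be split at its largest internal gap(s)
  base <- 500
  mzs <- base * (1 + c(0, 15, 30, 45) * 1e-6)
  secs <- lapply(seq_along(mzs), function(i) {
    section_dataset(list(mass_spectrum(mzs[i], 1, "positive",
                                       centroided = TRUE)),
                    1, 1, 120, section_index = i - 1)
  })
  dm <- bin_peaks(secs, tolerance_ppm = 20)
  expect_gt(ncol(dm$matrix), 1)
  expect_true(all(vapply(seq_len(ncol(dm$matrix)), function(b) {
    members <- mzs[dm$matrix[, b] > 0]
    !length(members) ||
      (max(members) - min(members)) / mean(members) * 1e6 <= 20
  }, logical(1))))
  expect_error(bin_peaks(list(), 20))
})
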