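test_that("phantom_spec validates noise, geometry and channels", {
  expect_s3_class(tiny_spec(), "phantom_spec")
  expect_error(tiny_spec(tic_cv = -0.1))
  expect_error(tiny_spec(mz_jitter_ppm = -1))
  # an in-plane overrun is rejected; a z overrun is allowed
  bad <- list(blob = list(
    label = "blob",
    geometry = list(type = "ellipsoid", center = c(5, 5, 2),
                    semi = c(30, 3, 1)),
    channels = list(positive = data.frame(mz = 500, intensity = 1))))
  expect_error(phantom_spec(shape = c(20L, 20L, 4L), regions = bad),
               "plane")
  ok <- bad
  ok$blob$geometry$semi <- c(3, 3, 50)
  expect_s3_class(phantom_spec(shape = c(20L, 20L, 4L), regions = ok),
                  "phantom_spec")
  neg <- ok
  neg$blob$channels$positive$intensity <- -1
  expect_error(phantom_spec(shape = c(20L, 20L, 4L), regions = neg))
})

test_that("build_phantom is deterministic in the seed", {
  t1 <- build_phantom(tiny_spec())
  t2 <- build_phantom(tiny_spec())
  expect_identical(t1$label_volume, t2$label_volume)
  expect_identical(t1$transforms, t2$transforms)
  t3 <- build_phantom(phantom_spec(shape = c(24L, 24L, 5L), seed = 43L))
  expect_false(identical(t2$transforms, t3$transforms))
  # section 0 is the untouched reference
  expect_equal(t1$transforms[[1]]$angle_deg, 0)
  expect_equal(t1$transforms[[1]]$tx_um, 0)
  # planted transforms respect the configured ranges
  for (tf in t1$transforms) {
    expect_lte(abs(tf$angle_deg), 10)
    expect_lte(max(abs(c(tf$tx_um, tf$ty_um))), 360)
  }
})

test_that("all three default regions cover voxels and carry channels", {
  truth <- build_phantom(tiny_spec())
  expect_equal(unname(truth$region_labels), c("viable", "hypoxic", "band"))
  for (code in 1:3) expect_gt(sum(truth$label_volume == code), 0)
  expect_true(all(c("positive", "negative") %in%
                    unique(truth$channels$polarity)))
  # the carnitine-band channels live in the band region
  band_pos <- truth$channels[truth$channels$region == "band" &
                               truth$channels$polarity == "positive", ]
  expect_true(all(c(400.3421, 428.3734, 369.2999) %in% band_pos$mz))
})

test_that("zero-noise render reproduces concentrations exactly", {
  spec <- tiny_spec(tic_cv = 0, additive_sd = 0, mz_jitter_ppm = 0,
                    rot_range_deg = 0, trans_range_um = 0)
  truth <- build_phantom(spec)
  secs <- render_sections(truth, "positive")
  expect_length(secs, 5)
  z <- 3
  img <- ion_image(secs[[z + 1]], 400.3421, tolerance_ppm = 30)
  conc <- truth$conc[["positive_400.3421"]][, , z + 1]
  expect_equal(img, conc)
  # spectra respect the acquisition mass range
  rng <- range(unlist(lapply(secs[[1]]$spectra, `[[`, "mz")))
  expect_gte(rng[1], 50)
  expect_lte(rng[2], 1200)
})

test_that("planted misalignment moves the rendered sections", {
  spec <- tiny_spec(tic_cv = 0, additive_sd = 0, mz_jitter_ppm = 0)
  truth <- build_phantom(spec)
  secs <- render_sections(truth, "positive")
  z <- 2
  img <- tic_image(secs[[z + 1]])
  # undoing the planted transform recovers the unmisaligned render
  aligned <- apply_transform(img, invert_transform(truth$transforms[[z + 1]]),
                             spec$pitch_um)
  spec0 <- tiny_spec(tic_cv = 0, additive_sd = 0, mz_jitter_ppm = 0,
                     rot_range_deg = 0, trans_range_um = 0)
  ref <- tic_image(render_sections(build_phantom(spec0), "positive")[[z + 1]])
  expect_false(isTRUE(all.equal(img, ref)))
  # interpolation smooths the sharp region edges, so compare by
  # correlation: undoing the transform must restore the structure
  ncc <- function(a, b) stats::cor(as.vector(a), as.vector(b))
  expect_gt(ncc(aligned, ref), 0.95)
  expect_gt(ncc(aligned, ref), ncc(img, ref) + 0.02)
})

test_that("fluorescence renders the stained regions on a finer grid", {
  spec <- tiny_spec(fluor_noise_sd = 0, fluor_background = 10)
  truth <- build_phantom(spec)
  z <- 2
  fl <- render_fluorescence(truth, z)
  f <- spec$fluor_fine_factor
  expect_equal(dim(fl), c(24 * f, 24 * f))
  # zero noise -> two-level map of background and stained level
  expect_setequal(unique(as.vector(fl)), c(10, 10 + 200))
  stained <- truth$label_volume[, , z + 1] %in%
    which(truth$region_labels %in% spec$fluor_regions)
  expect_equal(mean(fl > 10), mean(stained))
  expect_error(render_fluorescence(truth, 99))
})

test_that("write_phantom_truth writes text and NRRD sidecars", {
  truth <- build_phantom(tiny_spec())
  dir <- file.path(tempdir(), "truth_out")
  write_phantom_truth(truth, dir)
  expect_true(file.exists(file.path(dir, "transforms.csv")))
  expect_true(file.exists(file.path(dir, "channels.csv")))
  lab <- read_nrrd(file.path(dir, "labels.nrrd"))
  expect_equal(sum(lab$data > 0),
               sum(truth$label_volume > 0))
})
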